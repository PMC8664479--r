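#' Write a plant-level trait table (and generative truth) to disk
#'
#' Writes the table as plain CSV, one row per plant. When generative reaction
#' norms are supplied (synthetic data), a JSON sidecar records the true
#' parameters so recovery tests can compare fits against the truth.
#'
#' @param table Trait table data frame.
#' @param path Output CSV path.
#' @param norms Optional named list of [reaction_norm_spec()].
#' @param norms_path Sidecar path (default: `path` with `_truth.json`).
#' @return `path`, invisibly.
#' @export
write_trait_table <- function(table, path, norms = NULL, norms_path = NULL) {
  utils::write.csv(table, path, row.names = FALSE)
  if (!is.null(norms)) {
    if (is.null(norms_path)) {
      norms_path <- sub("\\.csv$", "", path)
      norms_path <- paste0(norms_path, "_truth.json")
    }
    jsonlite::write_json(lapply(norms, unclass), norms_path,
                         auto_unbox = TRUE, digits = NA)
  }
  invisible(path)
}

#' Read and validate a plant-level trait table
#'
#' Reads a CSV with one row per plant and validates it: the design columns
#' must be present, trait columns must be numeric (offending rows are named),
#' soil moisture must be positive, and every genotype must belong to exactly
#' one species. A per-trait, per-species missingness report is attached as
#' attribute `"validation"`.
#'
#' @param path CSV path.
#' @param traits Expected trait columns (default: every non-design column).
#' @return The validated data frame.
#' @export
read_trait_table <- function(path, traits = NULL) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  required <- c("plant_id", "species", "genotype", "cohort",
                "soil_moisture_final")
  missing_cols <- setdiff(required, names(tab))
  if (length(missing_cols)) {
    stop("trait table is missing required column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  meta <- c(required, "treatment", "harvest_group")
  if (is.null(traits)) traits <- setdiff(names(tab), meta)

  for (col in c("cohort", "soil_moisture_final", traits)) {
    v <- tab[[col]]
    if (is.character(v) || is.logical(v)) {
      suppressWarnings(conv <- as.numeric(v))
      bad <- which(!is.na(v) & v != "" & is.na(conv))
      if (length(bad)) {
        stop(sprintf("non-numeric values in column '%s' (rows: %s)", col,
                     paste(utils::head(bad, 10), collapse = ", ")))
      }
      tab[[col]] <- conv
    }
  }
  if (any(tab$soil_moisture_final <= 0, na.rm = TRUE)) {
    stop("`soil_moisture_final` must be positive")
  }
  gs <- unique(tab[, c("genotype", "species")])
  dup <- gs$genotype[duplicated(gs$genotype)]
  if (length(dup)) {
    stop("genotype(s) assigned to more than one species: ",
         paste(unique(dup), collapse = ", "))
  }

  miss <- do.call(rbind, lapply(sort(unique(tab$species)), function(sp) {
    d <- tab[tab$species == sp, , drop = FALSE]
    data.frame(species = sp, trait = traits,
               n_missing = vapply(traits, function(tr) sum(is.na(d[[tr]])),
                                  integer(1)),
               n = nrow(d), stringsAsFactors = FALSE)
  }))
  rownames(miss) <- NULL
  attr(tab, "validation") <- miss
  tab
}
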