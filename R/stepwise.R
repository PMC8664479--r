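#' Fit one reaction-norm term set for a trait
#'
#' Fits the fixed-effects model defined by `terms` to the non-missing rows of
#' one trait (optionally restricted to one species), freezing the spline knot
#' definition from the observed moisture values of those rows. This is the
#' state-free fitting primitive used by [stepwise_select()]; refitting a
#' selected term set reproduces the selected model's coefficients and AIC
#' exactly.
#'
#' @param data Trait table (see [simulate_dry_down()] / [read_trait_table()]).
#' @param trait Name of the trait column to model.
#' @param terms Character subset of [full_term_set()].
#' @param species Optional species label to subset on.
#' @param df Spline degrees of freedom for the `S` term.
#' @param basis Optional pre-computed [spline_basis_def()] (defaults to knots
#'   from the fitted rows).
#' @return An object of class `fvt_model`.
#' @export
fit_term_set <- function(data, trait, terms, species = NULL, df = 2,
                         basis = NULL) {
  terms <- check_terms(terms)
  if (!trait %in% names(data)) stop(sprintf("trait '%s' not in data", trait))
  d <- data
  if (!is.null(species)) {
    if (is.null(d$species)) stop("`data` has no species column")
    d <- d[d$species == species, , drop = FALSE]
    if (!nrow(d)) stop(sprintf("no rows for species '%s'", species))
  }
  d <- d[!is.na(d[[trait]]), , drop = FALSE]
  if (nrow(d) < 20) {
    warning(sprintf("trait '%s'%s has only %d non-missing rows", trait,
                    if (is.null(species)) "" else paste0(" (", species, ")"),
                    nrow(d)))
  }
  if (is.null(basis)) basis <- spline_basis_def(d$soil_moisture_final, df = df)
  genotype_levels <- if (!is.null(d$genotype)) {
    sort(unique(as.character(d$genotype)))
  }
  cohort_levels <- if (!is.null(d$cohort)) sort(unique(d$cohort))

  dm <- build_design_matrix(terms, d, basis = basis,
                            genotype_levels = genotype_levels,
                            cohort_levels = cohort_levels)
  fit <- fit_least_squares(dm$X, d[[trait]])
  structure(list(species = species, trait = trait, terms = terms,
                 basis = basis, coefficients = fit$coefficients,
                 aliased = fit$aliased, term_of = dm$term_of,
                 rank = fit$rank, n = fit$n, rss = fit$rss,
                 perfect_fit = fit$perfect_fit, aic = model_aic(fit),
                 genotype_levels = genotype_levels,
                 cohort_levels = cohort_levels),
            class = "fvt_model")
}

#' @export
print.fvt_model <- function(x, ...) {
  cat(sprintf("Reaction-norm model: %s%s\n", x$trait,
              if (is.null(x$species)) "" else paste0(" (", x$species, ")")))
  cat("  terms:", if (length(x$terms)) paste(x$terms, collapse = " + ")
      else "(intercept only)", "\n")
  cat(sprintf("  n = %d, rank = %d, AIC = %s\n", x$n, x$rank,
              format(x$aic, digits = 6)))
  invisible(x)
}

# A candidate move strictly improves on the current state if its AIC is
# lower; among perfect fits (AIC -Inf) the smaller rank wins. AIC differences
# below a small tolerance are treated as ties: refitting after removal of an
# exactly collinear (aliased) term reproduces the same AIC only up to
# floating-point noise, and a tolerance keeps such comparisons deterministic.
AIC_TIE_TOL <- 1e-7

improves <- function(cand_aic, cand_rank, cur_aic, cur_rank) {
  if (is.infinite(cand_aic) && is.infinite(cur_aic)) {
    return(cand_rank < cur_rank)
  }
  cand_aic < cur_aic - AIC_TIE_TOL
}

deletable <- function(term, terms) {
  !any(vapply(intersect(names(TERM_DEPS), terms),
              function(t) term %in% TERM_DEPS[[t]], logical(1)))
}

addable <- function(term, terms) {
  deps <- TERM_DEPS[[term]]
  is.null(deps) || all(deps %in% terms)
}

#' Bidirectional stepwise AIC selection of a reaction-norm model
#'
#' Starting from the full model, repeatedly enumerates all single-term
#' deletions and additions (scope limited to the full model's terms) that
#' respect marginality, refits each candidate, and applies the move with the
#' lowest AIC provided it is a strict improvement on the current model. Ties
#' among candidate moves are broken in favour of deletions over additions,
#' then by the canonical term order of [full_term_set()]. A perfect fit
#' (RSS = 0) has AIC `-Inf`; among perfect fits the search minimises rank, so
#' noise-free data recover the smallest exactly-fitting model.
#'
#' @inheritParams fit_term_set
#' @param full Term set to start from and the addition scope (default: all
#'   eight terms).
#' @param max_steps Safety cap on the number of accepted moves.
#' @param trace_all Keep every candidate evaluation in the trace (default
#'   keeps them; set `FALSE` to record accepted moves only).
#' @return An `fvt_model` with the selection `trace` attached (a data frame
#'   of evaluated moves: step, action, term, rank, AIC, accepted).
#' @export
#' @examples
#' sim <- simulate_dry_down(dry_down_design(n_plants_per_genotype = 30,
#'                                          n_genotypes_per_species = 3),
#'                          seed = 2, split_harvest = FALSE)
#' m <- stepwise_select(sim$table, "shoot_mass", species = "distachyon")
#' m$terms
stepwise_select <- function(data, trait, species = NULL,
                            full = full_term_set(), df = 2, max_steps = 50,
                            trace_all = TRUE) {
  full <- check_terms(full)
  cur <- fit_term_set(data, trait, full, species = species, df = df)
  basis <- cur$basis
  # reuse the subset and knots so every candidate sees identical data
  fit1 <- function(terms) {
    suppressWarnings(fit_term_set(data, trait, terms, species = species,
                                  df = df, basis = basis))
  }
  trace <- data.frame(step = 0L, action = "start", term = "",
                      rank = cur$rank, aic = cur$aic, accepted = TRUE,
                      stringsAsFactors = FALSE)
  for (step in seq_len(max_steps)) {
    moves <- list()
    for (t in canonical_terms(cur$terms)) {
      if (deletable(t, cur$terms)) {
        moves[[length(moves) + 1L]] <- list(action = "drop", term = t,
                                            terms = setdiff(cur$terms, t))
      }
    }
    for (t in setdiff(full, cur$terms)) {
      if (addable(t, cur$terms)) {
        moves[[length(moves) + 1L]] <- list(action = "add", term = t,
                                            terms = union(cur$terms, t))
      }
    }
    if (!length(moves)) break
    best <- NULL
    for (mv in moves) {
      cand <- fit1(mv$terms)
      if (trace_all) {
        trace <- rbind(trace, data.frame(step = step, action = mv$action,
                                         term = mv$term, rank = cand$rank,
                                         aic = cand$aic, accepted = FALSE,
                                         stringsAsFactors = FALSE))
      }
      if (is.null(best) || improves(cand$aic, cand$rank, best$aic, best$rank)) {
        best <- cand
        best_move <- mv
      }
    }
    if (improves(best$aic, best$rank, cur$aic, cur$rank)) {
      cur <- best
      if (trace_all) {
        hit <- trace$step == step & trace$action == best_move$action &
          trace$term == best_move$term
        trace$accepted[hit] <- TRUE
      } else {
        trace <- rbind(trace, data.frame(step = step,
                                         action = best_move$action,
                                         term = best_move$term,
                                         rank = cur$rank, aic = cur$aic,
                                         accepted = TRUE,
                                         stringsAsFactors = FALSE))
      }
    } else {
      break
    }
  }
  cur$trace <- trace
  cur
}

#' Select reaction-norm models for every trait and species
#'
#' Runs [stepwise_select()] separately per species and per trait (the two
#' species are analysed separately throughout). Traits whose selection fails
#' (e.g. all values missing) are dropped with a warning and recorded in the
#' result's `failures` attribute.
#'
#' @param data Trait table.
#' @param traits Trait columns to model (default: all columns after the
#'   design metadata).
#' @param species Species to include (default: all present).
#' @inheritParams stepwise_select
#' @return A named list of `fvt_model` (keys `"species.trait"`), class
#'   `fvt_model_set`.
#' @export
select_trait_models <- function(data, traits = NULL, species = NULL,
                                full = full_term_set(), df = 2,
                                max_steps = 50) {
  meta <- c("plant_id", "species", "genotype", "cohort", "treatment",
            "soil_moisture_final", "harvest_group")
  if (is.null(traits)) traits <- setdiff(names(data), meta)
  if (is.null(species)) {
    species <- if (is.null(data$species)) list(NULL) else
      sort(unique(data$species))
  }
  models <- list()
  failures <- character(0)
  for (sp in species) {
    for (tr in traits) {
      key <- paste(if (is.null(sp)) "all" else sp, tr, sep = ".")
      res <- tryCatch(
        stepwise_select(data, tr, species = sp, full = full, df = df,
                        max_steps = max_steps, trace_all = TRUE),
        error = function(e) e)
      if (inherits(res, "error")) {
        warning(sprintf("model selection failed for %s: %s", key,
                        conditionMessage(res)))
        failures <- c(failures, key)
      } else {
        models[[key]] <- res
      }
    }
  }
  structure(models, class = "fvt_model_set", failures = failures)
}

#' @export
print.fvt_model_set <- function(x, ...) {
  cat("Selected reaction-norm models (", length(x), " trait x species fits)\n",
      sep = "")
  print(term_matrix(x))
  invisible(x)
}

#' Term-selection matrix across fitted models
#'
#' Summarises which terms were retained in each selected model as a
#' trait-by-species table with `"x"` for present and `"-"` for absent,
#' one row per trait x species fit and one column per candidate term.
#'
#' @param models An `fvt_model_set` (or list of `fvt_model`).
#' @return Data frame with columns `species`, `trait`, then one column per
#'   term of [full_term_set()].
#' @export
term_matrix <- function(models) {
  rows <- lapply(models, function(m) {
    marks <- ifelse(FVT_TERMS %in% m$terms, "x", "-")
    out <- data.frame(species = if (is.null(m$species)) "all" else m$species,
                      trait = m$trait, stringsAsFactors = FALSE)
    out[FVT_TERMS] <- as.list(marks)
    out
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
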