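#' Derive composite traits from raw harvest measurements
#'
#' Computes the standard composite phenotypes from per-plant raw harvest
#' measurements:
#'
#' * `RWC = (mass_fresh - mass_dry_leaf) / (mass_turgid - mass_dry_leaf)`
#' * `SLA = leaf_area / mass_dry_leaf` (area per unit leaf dry mass)
#' * `root_shoot = root_mass / shoot_mass`
#' * `biomass = shoot_mass + root_mass`
#' * `C_N = C_content / N_content`
#'
#' Degenerate denominators (turgid mass equal to dry mass, zero shoot mass,
#' zero N) yield `NA` rather than infinities; each column is only computed
#' when its inputs are present.
#'
#' @param raw Data frame with any of the columns `mass_fresh`, `mass_turgid`,
#'   `mass_dry_leaf` (g), `leaf_area` (mm^2), `shoot_mass`, `root_mass` (g),
#'   `C_content`, `N_content` (% dry mass).
#' @return `raw` with derived columns appended.
#' @export
#' @examples
#' derive_traits(data.frame(mass_fresh = 0.9, mass_turgid = 1, mass_dry_leaf = 0.5))$RWC
derive_traits <- function(raw) {
  stopifnot(is.data.frame(raw))
  has <- function(...) all(c(...) %in% names(raw))
  num <- function(col) {
    v <- raw[[col]]
    if (!is.numeric(v)) stop(sprintf("column '%s' must be numeric", col))
    v
  }
  out <- raw

  if (has("mass_fresh", "mass_turgid", "mass_dry_leaf")) {
    fresh <- num("mass_fresh"); turgid <- num("mass_turgid")
    dry <- num("mass_dry_leaf")
    bad <- !is.na(dry) & (dry <= 0 | (!is.na(fresh) & fresh < dry) |
                            (!is.na(turgid) & turgid < fresh))
    if (any(bad, na.rm = TRUE)) {
      stop("raw leaf masses must satisfy turgid >= fresh >= dry > 0 (rows: ",
           paste(utils::head(which(bad), 5), collapse = ", "), ")")
    }
    denom <- turgid - dry
    out$RWC <- ifelse(denom > 0, (fresh - dry) / denom, NA_real_)
  }
  if (has("leaf_area", "mass_dry_leaf")) {
    area <- num("leaf_area"); dry <- num("mass_dry_leaf")
    if (any(area <= 0, na.rm = TRUE)) stop("`leaf_area` must be positive")
    out$SLA <- ifelse(dry > 0, area / dry, NA_real_)
  }
  if (has("shoot_mass", "root_mass")) {
    shoot <- num("shoot_mass"); root <- num("root_mass")
    if (any(shoot < 0, na.rm = TRUE) || any(root < 0, na.rm = TRUE)) {
      stop("shoot and root masses must be >= 0")
    }
    out$root_shoot <- ifelse(shoot > 0, root / shoot, NA_real_)
    out$biomass <- shoot + root
  }
  if (has("C_content", "N_content")) {
    out$C_N <- ifelse(num("N_content") != 0,
                      num("C_content") / num("N_content"), NA_real_)
  }
  out
}
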