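#' Derived cell-wall mechanics with propagated uncertainties
#'
#' From measured species-level summaries (bending stiffness `beta`, Young's
#' modulus `E`, gliding curvature `kappa`, radius `r`, each with a standard
#' deviation and measurement count) computes the derived quantities
#' \itemize{
#'   \item effective wall thickness `dr = beta / (pi E r^3)`,
#'   \item maximum wall stress `sigma_s = kappa E r`,
#'   \item bending energy density `U = beta kappa^2 / 2`
#' }
#' with standard errors by first-order (delta-method) propagation, treating
#' the inputs as independent and using `se = sd / sqrt(n)` for each.
#'
#' @param measured A data frame like [species_table()]: columns `beta`,
#'   `E`, `kappa`, `r` with `_sd` and `_n` companions (any extra columns
#'   are carried through).
#' @return The input with added columns `dr`, `dr_se` (m), `sigma_s`,
#'   `sigma_s_se` (Pa), `U`, `U_se` (J/m).
#' @examples
#' derive_summary(species_table())[, c("species", "dr", "sigma_s", "U")]
#' @export
derive_summary <- function(measured = species_table()) {
  need <- c("beta", "beta_sd", "beta_n", "E", "E_sd", "E_n",
            "kappa", "kappa_sd", "kappa_n", "r", "r_sd", "r_n")
  missing_cols <- setdiff(need, names(measured))
  if (length(missing_cols))
    .halt("schema error: missing columns ",
          paste(missing_cols, collapse = ", "))
  se <- function(q) measured[[paste0(q, "_sd")]] /
    sqrt(measured[[paste0(q, "_n")]])
  rel <- function(q) se(q) / measured[[q]]
  out <- measured
  out$dr <- measured$beta / (pi * measured$E * measured$r^3)
  out$dr_se <- out$dr * sqrt(rel("beta")^2 + rel("E")^2 + (3 * rel("r"))^2)
  out$sigma_s <- measured$kappa * measured$E * measured$r
  out$sigma_s_se <- out$sigma_s *
    sqrt(rel("kappa")^2 + rel("E")^2 + rel("r")^2)
  out$U <- 0.5 * measured$beta * measured$kappa^2
  out$U_se <- out$U * sqrt(rel("beta")^2 + (2 * rel("kappa"))^2)
  out
}

#' Correlation diagnostics for stiffness fits
#'
#' Rank (Spearman) and linear (Pearson) correlations of fitted stiffness
#' against the order in which flow conditions were applied (a plasticity
#' check), the filament length, and the flow speed — thin wrappers around
#' [stats::cor.test()] for report parity.
#'
#' @param fits A data frame with a `beta` column and one or more of
#'   `order`, `length`, `speed`.
#' @return A data frame with columns `predictor`, `method`, `estimate`,
#'   `p_value`, `n`.
#' @export
correlation_diagnostics <- function(fits) {
  if (!is.data.frame(fits) || !"beta" %in% names(fits))
    .halt("'fits' must be a data frame with a 'beta' column")
  if (nrow(fits) < 3L) .halt("need at least 3 rows")
  preds <- intersect(c("order", "length", "speed"), names(fits))
  if (length(preds) == 0L)
    .halt("no predictor columns (order, length, speed) found")
  rows <- list()
  for (p in preds) {
    if (length(unique(fits[[p]])) < 2L || length(unique(fits$beta)) < 2L) {
      warning("constant column: correlation with '", p, "' is undefined",
              call. = FALSE)
      next
    }
    for (m in c("spearman", "pearson")) {
      ct <- suppressWarnings(cor.test(fits$beta, fits[[p]], method = m))
      rows[[length(rows) + 1L]] <-
        data.frame(predictor = p, method = m,
                   estimate = unname(ct$estimate),
                   p_value = ct$p.value, n = nrow(fits))
    }
  }
  do.call(rbind, rows)
}
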