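#' Organ pools of the wheat canopy
#'
#' The four compartments into which whole-plant dry matter and nitrogen are
#' partitioned: stem, inferior leaves (Linf), flag leaf (L1) and ear. The
#' ordering is fixed and every 4-vector of organ values in the package follows
#' it.
#'
#' @return Character vector `c("stem", "linf", "l1", "ear")`.
#' @export
organs <- function() c("stem", "linf", "l1", "ear")

#' Canonical trait column names
#'
#' Column layout shared by reference CSV files, synthetic trajectories and
#' model targets: whole-plant traits followed by organ proportions of dry
#' matter and nitrogen uptake and the absolute nitrogen concentration of each
#' organ.
#'
#' @return Character vector of 16 column names.
#' @export
trait_columns <- function() {
  c("dm_total", "lai", "n_conc", "n_upt",
    paste0("dm_", organs()),
    paste0("nupt_", organs()),
    paste0("nconc_", organs()))
}

#' Construct a single trait vector
#'
#' Bundles the whole-plant traits (dry matter t/ha, LAI, nitrogen
#' concentration %, nitrogen uptake kgN/ha) with the per-organ partitioning.
#' Organ dry-matter and nitrogen-uptake values are proportions of the plant
#' total; organ nitrogen concentrations are absolute percentages, with an
#' absent organ encoded as 0.
#'
#' @param dm_total Dry matter of the whole plant, t/ha.
#' @param lai Leaf area index (dimensionless).
#' @param n_conc Whole-plant nitrogen concentration, percent of dry matter.
#' @param n_upt Nitrogen uptake, kgN/ha; defaults to `dm_total * n_conc * 10`.
#' @param dm_prop,nupt_prop Length-4 proportions over [organs()] summing to 1.
#' @param n_conc_organ Length-4 absolute %N per organ (0 where absent).
#' @return A named numeric vector with the [trait_columns()] layout, class
#'   `"trait_vector"`.
#' @export
trait_vector <- function(dm_total, lai, n_conc,
                         n_upt = dm_total * n_conc * 10,
                         dm_prop = rep(0.25, 4),
                         nupt_prop = dm_prop,
                         n_conc_organ = rep(n_conc, 4)) {
  x <- c(dm_total, lai, n_conc, n_upt, dm_prop, nupt_prop, n_conc_organ)
  names(x) <- trait_columns()
  class(x) <- "trait_vector"
  validate_traits(as.data.frame(as.list(unclass(x))))
  x
}

#' Validate trait invariants
#'
#' Checks, row by row, that organ proportions sum to one where the plant total
#' is positive, that all trait values are non-negative, and that the unit
#' identity Nupt = DM x %N x 10 (t/ha x percent -> kgN/ha) holds within
#' `identity_tol` relative error.
#'
#' @param df Data frame containing the [trait_columns()].
#' @param identity_tol Relative tolerance on the Nupt identity (default 1%).
#' @return `df`, invisibly; errors describe the first violated invariant.
#' @export
validate_traits <- function(df, identity_tol = 0.01) {
  need <- setdiff(trait_columns(), names(df))
  if (length(need))
    stop("missing trait columns: ", paste(need, collapse = ", "))
  num <- as.matrix(df[trait_columns()])
  if (any(!is.finite(num))) stop("non-finite trait values")
  if (any(num < -1e-9)) stop("negative trait values")
  dmp <- as.matrix(df[paste0("dm_", organs())])
  nup <- as.matrix(df[paste0("nupt_", organs())])
  i <- df$dm_total > 0
  if (any(i) && any(abs(rowSums(dmp[i, , drop = FALSE]) - 1) > 1e-6))
    stop("dm organ proportions do not sum to 1")
  j <- df$n_upt > 0
  if (any(j) && any(abs(rowSums(nup[j, , drop = FALSE]) - 1) > 1e-6))
    stop("nupt organ proportions do not sum to 1")
  k <- df$n_upt > 0 | df$dm_total * df$n_conc > 0
  if (any(k)) {
    expect <- df$dm_total[k] * df$n_conc[k] * 10
    rel <- abs(df$n_upt[k] - expect) / pmax(expect, 1e-9)
    if (any(rel > identity_tol))
      stop("Nupt identity (DM x %N x 10) violated beyond ",
           identity_tol * 100, "% at row ", which(k)[which.max(rel)])
  }
  invisible(df)
}

#' @export
print.trait_vector <- function(x, ...) {
  cat("wheat trait vector\n")
  v <- unclass(x)
  cat(sprintf("  DM %.2f t/ha | LAI %.2f | %%N %.2f | Nupt %.1f kgN/ha\n",
              v["dm_total"], v["lai"], v["n_conc"], v["n_upt"]))
  cat("  DM partition:  ",
      paste(sprintf("%s %.2f", organs(), v[paste0("dm_", organs())]),
            collapse = "  "), "\n")
  invisible(x)
}
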