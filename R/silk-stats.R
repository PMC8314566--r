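#' @include AllClasses.R
NULL

.checkNumericVec <- function(x, name, minLen) {
  if (!is.numeric(x) || length(x) < minLen || anyNA(x)) {
    .stopf("%s must be a numeric vector of length >= %d without NAs",
           name, minLen)
  }
}

#' Pearson product-moment correlation
#'
#' Standard Pearson correlation with a two-sided p-value from the
#' t-transform on n - 2 degrees of freedom (via [stats::cor.test()]).
#'
#' @param x,y numeric vectors of equal length >= 3, neither constant.
#' @return a [CorrelationResult-class].
#' @examples
#' pearsonR(c(1, 2, 3, 4), c(1, 3, 2, 4))   # r = 0.8
#' @export
pearsonR <- function(x, y) {
  .checkNumericVec(x, "x", 3)
  .checkNumericVec(y, "y", 3)
  if (length(x) != length(y)) .stopf("x and y must have equal length")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    .stopf("correlation undefined for a constant vector")
  }
  ct <- stats::cor.test(x, y, method = "pearson", alternative = "two.sided")
  methods::new("CorrelationResult",
               r = unname(ct$estimate), n = length(x),
               p = unname(ct$p.value))
}

#' Welch two-sample t-test
#'
#' Unequal-variance t-statistic with Welch-Satterthwaite degrees of freedom
#' and a two-sided p-value (via [stats::t.test()]). Welch rather than the
#' pooled-variance test because fibre groups typically have unequal sizes
#' and variances.
#'
#' @param a,b numeric vectors with at least two observations each.
#' @return a [TTestResult-class].
#' @export
welchT <- function(a, b) {
  .checkNumericVec(a, "a", 2)
  .checkNumericVec(b, "b", 2)
  if (stats::sd(a) == 0 && stats::sd(b) == 0 && mean(a) == mean(b)) {
    # degenerate identical constant groups: t = 0, p = 1 by convention
    return(methods::new("TTestResult", t = 0, df = length(a) + length(b) - 2,
                        p = 1, groupMeans = c(mean(a), mean(b))))
  }
  tt <- stats::t.test(a, b, var.equal = FALSE, alternative = "two.sided")
  methods::new("TTestResult",
               t = unname(tt$statistic), df = unname(tt$parameter),
               p = unname(tt$p.value), groupMeans = c(mean(a), mean(b)))
}

.MECH_PROPERTIES <- c("tensile_strength", "youngs_modulus",
                      "extensibility", "toughness")

.checkMechTable <- function(mech) {
  need <- c("species", .MECH_PROPERTIES)
  missing <- setdiff(need, names(mech))
  if (length(missing) > 0) {
    .stopf("mech table lacks column(s): %s", paste(missing, collapse = ", "))
  }
}

#' Crystallinity-mechanics trend across species
#'
#' Joins a fibre-mechanics table with per-species crystalline fractions,
#' averages the chosen property per species (one point per species, as when
#' relating structural fractions to fibre properties across silks), and
#' reports the Pearson correlation, the least-squares slope, and whether the
#' property decreases strictly monotonically with crystalline fraction.
#'
#' @param mech `data.frame` of per-fibre records (see
#'   [generateMechDataset()] for the column contract).
#' @param cryst `data.frame` with columns `species` and
#'   `crystalline_fraction`.
#' @param property one of `"tensile_strength"`, `"youngs_modulus"`,
#'   `"extensibility"`, `"toughness"`.
#' @param perFibre correlate per-fibre values instead of species means.
#' @return a [TrendResult-class].
#' @export
crystallinityTrend <- function(mech, cryst,
                               property = "tensile_strength",
                               perFibre = FALSE) {
  .checkMechTable(mech)
  property <- match.arg(property, .MECH_PROPERTIES)
  if (!all(c("species", "crystalline_fraction") %in% names(cryst))) {
    .stopf("cryst table needs columns 'species' and 'crystalline_fraction'")
  }
  means <- stats::aggregate(mech[[property]],
                            by = list(species = mech$species), FUN = mean)
  names(means)[2] <- property
  joined <- merge(means, cryst, by = "species")
  if (nrow(joined) < 3) {
    .stopf("need >= 3 species present in both tables (got %d)", nrow(joined))
  }
  joined <- joined[order(joined$crystalline_fraction), , drop = FALSE]
  rownames(joined) <- NULL

  if (perFibre) {
    fib <- merge(mech, cryst, by = "species")
    corr <- pearsonR(fib$crystalline_fraction, fib[[property]])
    fit <- stats::lm(fib[[property]] ~ fib$crystalline_fraction)
  } else {
    corr <- pearsonR(joined$crystalline_fraction, joined[[property]])
    fit <- stats::lm(joined[[property]] ~ joined$crystalline_fraction)
  }
  methods::new("TrendResult",
    property = property,
    r = corr@r, p = corr@p,
    slope = unname(stats::coef(fit)[2]),
    monotoneDecreasing = all(diff(joined[[property]]) < 0),
    speciesMeans = joined)
}

#' Per-species tensile-property summary
#'
#' @param mech `data.frame` of per-fibre records (columns `species`,
#'   `tensile_strength`, `youngs_modulus`, `extensibility`, `toughness`).
#' @return a `data.frame` with one row per species x property: `n`, `mean`,
#'   `sd` (0 when n = 1, flagged by `singleFibre`), `min`, `max`; rows
#'   ordered by species then property.
#' @export
tensileSummary <- function(mech) {
  .checkMechTable(mech)
  if (nrow(mech) == 0) .stopf("mech table must contain >= 1 record")
  rows <- list()
  for (sp in sort(unique(mech$species))) {
    sub <- mech[mech$species == sp, , drop = FALSE]
    for (prop in .MECH_PROPERTIES) {
      v <- sub[[prop]]
      rows[[length(rows) + 1L]] <- data.frame(
        species = sp, property = prop, n = length(v),
        mean = mean(v), sd = if (length(v) > 1) stats::sd(v) else 0,
        min = min(v), max = max(v),
        singleFibre = length(v) == 1L)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
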