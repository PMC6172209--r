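# Group summaries: mean +/- SEM, two-sample t tests against the untreated
# group, and the fixed significance tiers.

#' Mean and standard error of the mean
#'
#' @param x numeric vector, `length(x) >= 2`.
#' @return named numeric `c(mean, sem)` with `sem = sd(x) / sqrt(n)` (n - 1
#'   denominator sd).
#' @examples
#' meanSEM(c(1, 2, 3)) # mean 2, sem 1/sqrt(3)
#' @export
meanSEM <- function(x) {
  x <- as.numeric(x)
  if (length(x) < 2) stop("SEM undefined for fewer than 2 values")
  c(mean = mean(x), sem = stats::sd(x) / sqrt(length(x)))
}

#' Two-sample t test
#'
#' Unpaired two-tailed t test; `"student"` pools the variance
#' (df = n1 + n2 - 2), `"welch"` uses the Welch-Satterthwaite df. Degenerate
#' zero-variance inputs are handled explicitly: equal means give t = 0,
#' p = 1; unequal means with zero variance give p = 0 with a warning.
#'
#' @param a,b numeric vectors, each of length >= 2.
#' @param variant `"student"` (default, the classical pooled test) or
#'   `"welch"`.
#' @return named numeric `c(t, df, p)`.
#' @examples
#' twoSampleT(c(1, 2, 3), c(4, 5, 6)) # t = -3.674, df = 4, p = 0.0213
#' @export
twoSampleT <- function(a, b, variant = c("student", "welch")) {
  variant <- match.arg(variant)
  a <- as.numeric(a); b <- as.numeric(b)
  if (length(a) < 2 || length(b) < 2)
    stop("each group needs at least 2 values")
  if (stats::var(a) == 0 && stats::var(b) == 0) {
    df <- if (variant == "student") length(a) + length(b) - 2 else NA_real_
    if (mean(a) == mean(b))
      return(c(t = 0, df = df, p = 1))
    warning("zero variance in both groups with unequal means: p -> 0")
    return(c(t = sign(mean(a) - mean(b)) * Inf, df = df, p = 0))
  }
  ht <- stats::t.test(a, b, var.equal = variant == "student",
                      alternative = "two.sided")
  c(t = unname(ht$statistic), df = unname(ht$parameter),
    p = unname(ht$p.value))
}

#' Significance tier of a p value
#'
#' Closed thresholds: `****` p <= 0.0001, `***` p <= 0.001, `**` p <= 0.01,
#' `*` p <= 0.05, otherwise `ns`.
#'
#' @param p numeric vector of p values in `[0, 1]`.
#' @return character vector of tiers.
#' @export
significanceTier <- function(p) {
  if (any(is.na(p)) || any(p < 0 | p > 1))
    stop("p values must lie in [0, 1]")
  vapply(p, function(pp)
    if (pp <= 0.0001) "****" else if (pp <= 0.001) "***"
    else if (pp <= 0.01) "**" else if (pp <= 0.05) "*" else "ns",
    character(1))
}

#' Per-dose group summary with t tests against the untreated group
#'
#' Summarizes one band's values (raw intensity or percent) per dose: n,
#' mean, SEM, and an unpaired t test of each treated dose against the
#' untreated group, with significance tiers. Technical replicates are, by
#' default, averaged within their biological replicate first, so the test's
#' unit is the biological replicate.
#'
#' @param tbl band table from [quantifyBands()] /
#'   [percentOfUntreated()].
#' @param band band name to summarize.
#' @param value column to summarize: `"percent"` (default) or
#'   `"intensity"`.
#' @param aggregateTechnical average technical replicates within biological
#'   replicate before testing (default TRUE).
#' @param variant t-test variant, see [twoSampleT()].
#' @param untreatedDose dose labelling the untreated reference group.
#' @return data.frame per (cell line x) dose: `n`, `mean`, `sem`, `t`,
#'   `df`, `p`, `tier` (NA for the untreated row).
#' @export
groupSummary <- function(tbl, band, value = c("percent", "intensity"),
                         aggregateTechnical = TRUE,
                         variant = c("student", "welch"), untreatedDose = 0) {
  value <- match.arg(value); variant <- match.arg(variant)
  if (!value %in% colnames(tbl))
    stop("column '", value, "' not present; run percentOfUntreated() first?")
  sub <- tbl[tbl$band == band, ]
  if (!nrow(sub)) stop("band '", band, "' not present in the table")
  if (aggregateTechnical && all(c("bio_rep", "tech_rep") %in% colnames(sub))) {
    key <- interaction(sub[intersect(c("cell_line", "dose", "bio_rep"),
                                     colnames(sub))], drop = TRUE)
    agg <- stats::aggregate(sub[[value]], list(key = key), mean)
    info <- sub[!duplicated(key), intersect(c("cell_line", "dose", "bio_rep"),
                                            colnames(sub)), drop = FALSE]
    sub <- cbind(info[match(agg$key, key[!duplicated(key)]), , drop = FALSE],
                 value = agg$x)
  } else {
    sub$value <- sub[[value]]
  }
  split <- if ("cell_line" %in% colnames(sub)) split(sub, sub$cell_line)
           else list(sub)
  out <- lapply(split, function(g) {
    ut <- g$value[g$dose == untreatedDose]
    if (!length(ut)) stop("no untreated group to test against")
    res <- lapply(sort(unique(g$dose)), function(d) {
      v <- g$value[g$dose == d]
      ms <- meanSEM(v)
      if (d == untreatedDose) {
        data.frame(dose = d, n = length(v), mean = ms[["mean"]],
                   sem = ms[["sem"]], t = NA_real_, df = NA_real_,
                   p = NA_real_, tier = NA_character_)
      } else {
        tt <- twoSampleT(v, ut, variant)
        data.frame(dose = d, n = length(v), mean = ms[["mean"]],
                   sem = ms[["sem"]], t = tt[["t"]], df = tt[["df"]],
                   p = tt[["p"]], tier = significanceTier(tt[["p"]]))
      }
    })
    r <- do.call(rbind, res)
    if (!is.null(g$cell_line)) r <- cbind(cell_line = g$cell_line[1], r)
    r
  })
  res <- do.call(rbind, out); rownames(res) <- NULL
  res
}
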