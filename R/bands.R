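# Marker-band quantification: band table, peak picking on absorbance and
# second-derivative spectra, percent-of-untreated scaling, and the derived
# macromolecular statistics (Z-DNA enhancement, lipid unsaturation, amide I
# secondary-structure conversion).

#' Default marker-band assignment table
#'
#' The marker bands quantified by the analysis. `source` selects the
#' representation the intensity is read from: `absorbance` bands are peak
#' maxima of vector-normalized absorbance spectra; `second_derivative` bands
#' are magnitudes of the negative lobe (band maxima appear as second
#' derivative minima) of vector-normalized second-derivative spectra.
#' Search windows default to the band center +/- 4 cm^-1 (the instrument
#' resolution), except Z-DNA (1071-1061 cm^-1) and the PO2- antisymmetric
#' envelope (1242-1238 cm^-1). The PO2- symmetric band (~1080 cm^-1) is
#' shipped but disabled by default.
#'
#' @param includeDisabled logical; include disabled assignments.
#' @return data.frame with columns `band`, `center`, `window_high`,
#'   `window_low`, `source`, `class`, `enabled`.
#' @export
defaultBandAssignments <- function(includeDisabled = FALSE) {
  a <- function(band, center, class, source = "second_derivative",
                win = c(center + 4, center - 4), enabled = TRUE)
    data.frame(band = band, center = center, window_high = max(win),
               window_low = min(win), source = source, class = class,
               enabled = enabled, stringsAsFactors = FALSE)
  tbl <- rbind(
    a("po2_antisym", 1240, "nucleic_acid", source = "absorbance",
      win = c(1242, 1238)),
    a("ribose",       915, "nucleic_acid"),
    a("adna",        1240, "dna_form"),
    a("bdna",        1221, "dna_form"),
    a("zdna",        1066, "dna_form", win = c(1071, 1061)),
    a("alpha_1657",  1657, "protein"),
    a("alpha_1649",  1649, "protein"),
    a("beta_1636",   1636, "protein"),
    a("beta_1629",   1629, "protein"),
    a("olefinic",    3009, "lipid"),
    a("ch2_antisym", 2921, "lipid"),
    a("ch2_sym",     2852, "lipid"),
    a("chol_ester",  1172, "lipid"),
    a("po2_sym",     1080, "nucleic_acid", enabled = FALSE))
  if (!includeDisabled) tbl <- tbl[tbl$enabled, ]
  rownames(tbl) <- NULL
  tbl
}

#' Peak wavenumber and intensity of one marker band
#'
#' For `source = "absorbance"` the intensity is the maximum value inside the
#' search window; for `source = "second_derivative"` it is the magnitude of
#' the minimum (the negative lobe). Ties are broken toward the assignment's
#' literature center. The spectra in `x` must already be in the matching
#' representation and vector-normalized.
#'
#' @param x an [IRSpectraSet-class] in the assignment's source
#'   representation.
#' @param assignment one-row data.frame (or list) with `center`,
#'   `window_high`, `window_low` and `source` (see
#'   [defaultBandAssignments()]).
#' @return data.frame with one row per sample: `sample_id`,
#'   `peak_wavenumber`, `intensity`.
#' @export
bandIntensity <- function(x, assignment) {
  wn <- wavenumbers(x)
  idx <- .regionIdx(wn, c(assignment$window_low, assignment$window_high))
  if (!length(idx))
    stop("search window for band at ", assignment$center,
         " cm-1 lies outside the grid")
  Y <- intensities(x)[idx, , drop = FALSE]
  if (identical(assignment$source, "absorbance")) {
    val <- Y
  } else if (identical(assignment$source, "second_derivative")) {
    val <- -Y                                  # minima become maxima
  } else stop("unknown band source: ", assignment$source)
  pick <- apply(val, 2, function(v) {
    best <- which(v == max(v))
    if (length(best) > 1)                      # tie: toward literature center
      best <- best[which.min(abs(wn[idx][best] - assignment$center))]
    best
  })
  data.frame(sample_id = colnames(intensities(x)),
             peak_wavenumber = wn[idx][pick],
             intensity = pmax(val[cbind(pick, seq_len(ncol(val)))], 0),
             row.names = NULL)
}

#' Quantify all marker bands of a spectrum set
#'
#' Runs the standard quantification chain on raw spectra: scaled-reference
#' subtraction (if a reference is available and the spectra are not yet
#' background-subtracted), then two representations -- vector-normalized
#' absorbance, and Savitzky-Golay second derivative followed by vector
#' normalization -- and reads every enabled band from its source
#' representation.
#'
#' @param x an [IRSpectraSet-class] (raw or background-subtracted).
#' @param reference optional buffer reference spectrum (numeric vector or
#'   1-column set); default `metadata(x)$reference`.
#' @param assignments band table, default [defaultBandAssignments()].
#' @param sgWindow,sgOrder Savitzky-Golay parameters (default 9, 3).
#' @return data.frame with one row per sample x band: sample metadata,
#'   `band`, `class`, `source`, `peak_wavenumber`, `intensity`.
#' @export
quantifyBands <- function(x, reference = NULL,
                          assignments = defaultBandAssignments(),
                          sgWindow = 9, sgOrder = 3) {
  if (is.null(reference)) reference <- metadata(x)$reference
  if (!.hasStep(x, "background_subtracted") && !is.null(reference))
    x <- subtractReference(x, reference)
  absNorm <- vectorNormalize(x)
  sdNorm <- vectorNormalize(
    savgolDerivative(x, windowPoints = sgWindow, polyOrder = sgOrder, deriv = 2))
  cd <- as.data.frame(colData(x))
  keep <- intersect(c("sample_id", "cell_line", "dose", "bio_rep", "tech_rep"),
                    colnames(cd))
  out <- lapply(seq_len(nrow(assignments)), function(i) {
    b <- assignments[i, ]
    src <- if (b$source == "absorbance") absNorm else sdNorm
    r <- bandIntensity(src, b)
    cbind(cd[match(r$sample_id, cd$sample_id), keep, drop = FALSE],
          band = b$band, class = b$class, source = b$source,
          r[c("peak_wavenumber", "intensity")])
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

# group key for percent normalization: per cell line when present
.groupKey <- function(tbl) {
  if ("cell_line" %in% colnames(tbl))
    interaction(tbl$cell_line, tbl$band, drop = TRUE)
  else factor(tbl$band)
}

#' Percent-of-untreated scaling of band intensities
#'
#' Scales each band's raw intensities so that the untreated (dose 0) group
#' mean equals exactly 100 percent, per band (and per cell line when
#' present).
#'
#' @param tbl band intensity table from [quantifyBands()].
#' @param untreatedDose dose value labelling the untreated group (default 0).
#' @return `tbl` with an added `percent` column.
#' @export
percentOfUntreated <- function(tbl, untreatedDose = 0) {
  stopifnot(all(c("dose", "band", "intensity") %in% colnames(tbl)))
  if (!any(tbl$dose == untreatedDose))
    stop("no untreated (dose ", untreatedDose, ") samples present")
  key <- .groupKey(tbl)
  ut <- tbl$dose == untreatedDose
  utMean <- tapply(tbl$intensity[ut], key[ut], mean)
  if (anyNA(utMean[levels(key)]))
    stop("some bands have no untreated samples")
  if (any(utMean <= 0))
    stop("untreated mean intensity is zero for band(s): ",
         paste(names(utMean)[utMean <= 0], collapse = ", "))
  tbl$percent <- as.numeric(100 * tbl$intensity / utMean[as.character(key)])
  tbl
}

.bandWide <- function(tbl, bandNames) {
  miss <- setdiff(bandNames, tbl$band)
  if (length(miss))
    stop("band(s) missing from the intensity table: ",
         paste(miss, collapse = ", "))
  sub <- tbl[tbl$band %in% bandNames, ]
  keep <- intersect(c("sample_id", "cell_line", "dose", "bio_rep", "tech_rep"),
                    colnames(sub))
  ids <- unique(sub[keep])
  for (b in bandNames)
    ids[[b]] <- sub$intensity[sub$band == b][match(ids$sample_id,
                  sub$sample_id[sub$band == b])]
  ids
}

.summarize <- function(value, group) {
  n <- tapply(value, group, length)
  data.frame(dose = as.numeric(names(n)), n = as.integer(n),
             mean = as.numeric(tapply(value, group, mean)),
             sem = as.numeric(tapply(value, group, function(v)
               if (length(v) > 1) stats::sd(v) / sqrt(length(v)) else NA_real_)),
             row.names = NULL)
}

#' Z-DNA enhancement ratio per dose
#'
#' Per-sample ratio `r = I_Z / (I_A + I_B)` of the Z-DNA marker band
#' (1066 cm^-1) to the sum of the A-form (1240 cm^-1) and B-form
#' (1221 cm^-1) markers, reported per dose as the fold change of the group
#' mean ratio over the untreated mean ratio (untreated fold = 1 by
#' construction). Being a within-sample ratio, it is invariant to the
#' spectrum normalization.
#'
#' @param tbl band intensity table from [quantifyBands()].
#' @param untreatedDose dose labelling the untreated group.
#' @return data.frame per (cell line x) dose: `n`, `ratio_mean`,
#'   `ratio_sem`, `fold_change`.
#' @export
zdnaEnhancementRatio <- function(tbl, untreatedDose = 0) {
  w <- .bandWide(tbl, c("zdna", "adna", "bdna"))
  den <- w$adna + w$bdna
  if (any(den <= 0))
    stop("A-DNA + B-DNA intensity is zero: Z/(A+B) ratio undefined")
  w$ratio <- w$zdna / den
  split <- if ("cell_line" %in% colnames(w)) split(w, w$cell_line) else list(w)
  out <- lapply(split, function(g) {
    s <- .summarize(g$ratio, g$dose)
    utMean <- s$mean[s$dose == untreatedDose]
    if (!length(utMean)) stop("no untreated group for fold-change reference")
    s$ratio_mean <- s$mean; s$ratio_sem <- s$sem
    s$fold_change <- s$mean / utMean
    if (!is.null(g$cell_line)) s <- cbind(cell_line = g$cell_line[1], s)
    s[setdiff(colnames(s), c("mean", "sem"))]
  })
  res <- do.call(rbind, out); rownames(res) <- NULL
  res
}

#' Lipid unsaturation summary per dose
#'
#' Total lipid is the sum of the percent intensities of the olefinic
#' (3009 cm^-1), CH2 antisymmetric (2921 cm^-1), CH2 symmetric (2852 cm^-1)
#' and cholesteryl ester (1172 cm^-1) bands; the olefinic/total-lipid ratio
#' (x 100) tracks acyl-chain unsaturation independent of total lipid
#' content. Reported per dose as group mean +/- SEM of the olefinic percent
#' intensity and of the ratio.
#'
#' @param tbl band table with a `percent` column (see
#'   [percentOfUntreated()]).
#' @return data.frame per (cell line x) dose with `olefinic_mean/sem` and
#'   `olefinic_total_mean/sem` (both percent).
#' @export
lipidUnsaturationSummary <- function(tbl) {
  if (!"percent" %in% colnames(tbl))
    stop("run percentOfUntreated() first: a 'percent' column is required")
  p <- tbl; p$intensity <- p$percent    # summarize percent intensities
  w <- .bandWide(p, c("olefinic", "ch2_antisym", "ch2_sym", "chol_ester"))
  total <- w$olefinic + w$ch2_antisym + w$ch2_sym + w$chol_ester
  if (any(total <= 0)) stop("total lipid intensity is zero")
  w$ratio <- 100 * w$olefinic / total
  split <- if ("cell_line" %in% colnames(w)) split(w, w$cell_line) else list(w)
  out <- lapply(split, function(g) {
    s1 <- .summarize(g$olefinic, g$dose)
    s2 <- .summarize(g$ratio, g$dose)
    r <- data.frame(dose = s1$dose, n = s1$n,
                    olefinic_mean = s1$mean, olefinic_sem = s1$sem,
                    olefinic_total_mean = s2$mean, olefinic_total_sem = s2$sem)
    if (!is.null(g$cell_line)) r <- cbind(cell_line = g$cell_line[1], r)
    r
  })
  res <- do.call(rbind, out); rownames(res) <- NULL
  res
}

#' Amide I secondary-structure summary per dose
#'
#' Per sample, total alpha-helix intensity is `I(1657) + I(1649)` and total
#' beta-sheet intensity `I(1636) + I(1629)`, read from the second-derivative
#' representation within the amide I region. The alpha-to-beta conversion at
#' each dose is the relative loss of mean alpha intensity versus untreated,
#' `100 * (1 - mean alpha(dose) / mean alpha(UT))`; the beta gain
#' `100 * (mean beta(dose) / mean beta(UT) - 1)` is reported as a
#' consistency diagnostic.
#'
#' @param tbl band intensity table from [quantifyBands()].
#' @param untreatedDose dose labelling the untreated group.
#' @return data.frame per (cell line x) dose: `n`, `alpha_mean`,
#'   `alpha_sem`, `beta_mean`, `beta_sem`, `conversion_pct`, `beta_gain_pct`.
#' @export
secondaryStructureSummary <- function(tbl, untreatedDose = 0) {
  w <- .bandWide(tbl, c("alpha_1657", "alpha_1649", "beta_1636", "beta_1629"))
  w$alpha <- w$alpha_1657 + w$alpha_1649
  w$beta <- w$beta_1636 + w$beta_1629
  split <- if ("cell_line" %in% colnames(w)) split(w, w$cell_line) else list(w)
  out <- lapply(split, function(g) {
    sa <- .summarize(g$alpha, g$dose)
    sb <- .summarize(g$beta, g$dose)
    utA <- sa$mean[sa$dose == untreatedDose]
    utB <- sb$mean[sb$dose == untreatedDose]
    if (!length(utA) || utA <= 0)
      stop("untreated mean alpha intensity missing or zero")
    r <- data.frame(dose = sa$dose, n = sa$n,
                    alpha_mean = sa$mean, alpha_sem = sa$sem,
                    beta_mean = sb$mean, beta_sem = sb$sem,
                    conversion_pct = 100 * (1 - sa$mean / utA),
                    beta_gain_pct = 100 * (sb$mean / utB - 1))
    if (!is.null(g$cell_line)) r <- cbind(cell_line = g$cell_line[1], r)
    r
  })
  res <- do.call(rbind, out); rownames(res) <- NULL
  res
}
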