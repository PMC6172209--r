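# Interchange formats: long-format CSV (canonical) and a minimal read-only
# JCAMP-DX parser for instrument interoperability.

#' Write a spectrum set as long-format CSV
#'
#' Canonical interchange format: one row per (sample, wavenumber) with
#' columns `sample_id`, any design columns present (`cell_line`, `dose`,
#' `bio_rep`, `tech_rep`), `wavenumber`, `absorbance`, written at full
#' precision so a write/read round trip is bit-identical.
#'
#' @param x an [IRSpectraSet-class].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
writeSpectraCSV <- function(x, path) {
  wn <- wavenumbers(x)
  Y <- intensities(x)
  cd <- as.data.frame(colData(x))
  keep <- intersect(c("sample_id", "cell_line", "dose", "bio_rep", "tech_rep"),
                    colnames(cd))
  long <- cbind(cd[rep(seq_len(ncol(Y)), each = length(wn)), keep, drop = FALSE],
                wavenumber = rep(wn, times = ncol(Y)),
                absorbance = as.vector(Y))
  utils::write.csv(format(long, digits = 17, trim = TRUE, scientific = FALSE),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a spectrum set from long-format CSV
#'
#' Expects the dialect of [writeSpectraCSV()]. Spectra are placed on the
#' common grid of the first sample; samples on a different grid are linearly
#' interpolated onto it (with a message). Ascending grids are reordered to
#' the descending convention.
#'
#' @param path CSV file path.
#' @return An [IRSpectraSet-class].
#' @export
readSpectraCSV <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  long <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("sample_id", "wavenumber", "absorbance")
  miss <- setdiff(need, colnames(long))
  if (length(miss))
    stop("malformed spectra CSV, missing column(s): ", paste(miss, collapse = ", "))
  if (!nrow(long)) stop("empty spectra file: ", path)
  ids <- unique(long$sample_id)
  ref <- long$wavenumber[long$sample_id == ids[1]]
  if (is.unsorted(rev(ref), strictly = TRUE)) {
    o <- order(ref, decreasing = TRUE)
    if (anyDuplicated(ref)) stop("duplicate wavenumbers for sample ", ids[1])
    ref <- ref[o]
    message("reordering wavenumbers of the reference grid to descending")
  }
  Y <- vapply(ids, function(id) {
    g <- long[long$sample_id == id, ]
    if (isTRUE(all.equal(g$wavenumber, ref))) return(g$absorbance)
    message("sample ", id, ": interpolating onto the common grid")
    stats::approx(g$wavenumber, g$absorbance, xout = ref, rule = 2)$y
  }, numeric(length(ref)))
  metaCols <- intersect(c("cell_line", "dose", "bio_rep", "tech_rep"),
                        colnames(long))
  cd <- long[!duplicated(long$sample_id), c("sample_id", metaCols), drop = FALSE]
  IRSpectraSet(Y, ref, cd[match(ids, cd$sample_id), , drop = FALSE])
}

# decode one AFFN/PAC numeric line of a JCAMP XYDATA block
.jcampLineY <- function(line) {
  toks <- strsplit(trimws(line), "[ \t,;]+")[[1]]
  as.numeric(unlist(strsplit(toks, "(?<=[0-9.])(?=[+-])", perl = TRUE)))
}

#' Read a single-spectrum JCAMP-DX file
#'
#' Minimal read-only parser for fixed-increment `##XYDATA=(X++(Y..Y))`
#' blocks in AFFN form (plain numbers; SQZ/DIF compression is not
#' supported). `##XFACTOR`, `##YFACTOR`, `##FIRSTX`, `##LASTX` and
#' `##NPOINTS` are honoured; ascending records are reordered to the
#' descending convention.
#'
#' @param path JCAMP-DX file path.
#' @param sample_id sample identifier; default the file's `##TITLE`.
#' @return An [IRSpectraSet-class] with one spectrum.
#' @export
readJCAMP <- function(path, sample_id = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!grepl("^\\$\\$", lines)]
  label <- function(nm) {
    i <- grep(paste0("^##", nm, "="), lines, ignore.case = TRUE)
    if (!length(i)) return(NULL)
    sub(paste0("^##", nm, "="), "", lines[i[1]], ignore.case = TRUE)
  }
  getNum <- function(nm, default = NULL) {
    v <- label(nm)
    if (is.null(v)) return(default)
    as.numeric(trimws(v))
  }
  xf <- getNum("XFACTOR", 1); yf <- getNum("YFACTOR", 1)
  firstx <- getNum("FIRSTX"); lastx <- getNum("LASTX")
  npt <- getNum("NPOINTS")
  xun <- label("XUNITS")
  if (!is.null(xun) && !grepl("1/CM|CM-1|WAVENUMBER", toupper(xun)))
    stop("unsupported JCAMP x units: ", trimws(xun))
  i0 <- grep("^##XYDATA=", lines, ignore.case = TRUE)
  if (!length(i0)) stop("no ##XYDATA block found in ", path)
  form <- toupper(gsub("\\s", "", sub("^##XYDATA=", "", lines[i0[1]],
                                      ignore.case = TRUE)))
  if (form != "(X++(Y..Y))")
    stop("unsupported XYDATA form: ", form)
  iEnd <- grep("^##", lines)
  iEnd <- c(iEnd[iEnd > i0[1]], length(lines) + 1)[1]
  block <- lines[(i0[1] + 1):(iEnd - 1)]
  block <- block[nzchar(trimws(block))]
  ys <- unlist(lapply(block, function(l) .jcampLineY(l)[-1]))
  if (anyNA(ys)) stop("malformed numeric data in JCAMP XYDATA block")
  if (is.null(firstx) || is.null(lastx))
    stop("JCAMP file lacks FIRSTX/LASTX")
  if (!is.null(npt) && npt != length(ys))
    stop("JCAMP NPOINTS (", npt, ") disagrees with data length (",
         length(ys), ")")
  wn <- seq(firstx * xf, lastx * xf, length.out = length(ys))
  y <- ys * yf
  if (wn[1] < wn[length(wn)]) {        # ascending: reorder
    message("reordering ascending JCAMP record to descending wavenumbers")
    o <- order(wn, decreasing = TRUE)
    wn <- wn[o]; y <- y[o]
  }
  if (is.null(sample_id)) {
    sample_id <- label("TITLE")
    if (is.null(sample_id) || !nzchar(trimws(sample_id))) sample_id <- "jcamp"
    sample_id <- trimws(sample_id)
  }
  IRSpectraSet(matrix(y, ncol = 1), wn,
               data.frame(sample_id = sample_id))
}
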