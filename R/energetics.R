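# Per-residue energy analysis: parsing FoldX SequenceDetail tables,
# residue x time-window ddG matrices, residue-class annotation, and the
# ddG vs solvent-accessibility regression. FoldX itself is never run;
# only its text output is consumed.

#' Parse a FoldX SequenceDetail per-residue energy table
#'
#' Accepts the whitespace-separated layout
#' `<3-letter residue> <chain> <residue number> <total energy> [...]`
#' after an optional header line. One record per residue.
#'
#' @param path Text file path.
#' @return data.frame with columns `resname`, `chain`, `resid`, `energy`.
#' @export
parse_foldx_sequence_detail <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0) stop("empty SequenceDetail file: ", path)
  rows <- list()
  for (k in seq_along(lines)) {
    tok <- strsplit(trimws(lines[k]), "\\s+")[[1]]
    if (k == 1 && !toupper(tok[1]) %in% .AA3) next  # header line
    if (length(tok) < 4 || !toupper(tok[1]) %in% .AA3 ||
        is.na(suppressWarnings(as.integer(tok[3]))) ||
        is.na(suppressWarnings(as.numeric(tok[4])))) {
      stop(sprintf("malformed SequenceDetail row at line %d: %s",
                   k, lines[k]))
    }
    rows[[length(rows) + 1L]] <- data.frame(
      resname = toupper(tok[1]), chain = tok[2],
      resid = as.integer(tok[3]), energy = as.numeric(tok[4]),
      stringsAsFactors = FALSE)
  }
  if (length(rows) == 0) stop("no residue rows in SequenceDetail file")
  do.call(rbind, rows)
}

#' Assemble a residue x window energy matrix
#'
#' @param records Named list of per-window record data.frames (as from
#'   [parse_foldx_sequence_detail()]); list names become window labels.
#'   Per-residue energies are averaged when a window holds replicate
#'   records for the same residue (replicate averaging before any ddG).
#' @param residues Residue numbers expected (default 1:42). Missing
#'   entries are NA, never silently zero.
#' @return Numeric matrix (residues x windows) with dimnames.
#' @export
energy_matrix <- function(records, residues = 1:42) {
  stopifnot(is.list(records), length(records) >= 1)
  wnames <- names(records)
  if (is.null(wnames)) wnames <- paste0("w", seq_along(records))
  m <- matrix(NA_real_, length(residues), length(records),
              dimnames = list(residues, wnames))
  for (w in seq_along(records)) {
    r <- records[[w]]
    mean_e <- tapply(r$energy, r$resid, mean)
    idx <- match(as.integer(names(mean_e)), residues)
    m[idx[!is.na(idx)], w] <- mean_e[!is.na(idx)]
  }
  m
}

#' Per-residue, per-window ddG between two conditions
#'
#' Elementwise `treated - control`; positive values mean the residue is
#' less favorable in the treated (lipid-exposed) condition.
#'
#' @param control,treated Numeric matrices with identical dimnames (as
#'   from [energy_matrix()]).
#' @return Matrix of the same shape.
#' @export
ddg_matrix <- function(control, treated) {
  if (!identical(dimnames(control), dimnames(treated))) {
    stop("row/column labels of control and treated matrices differ")
  }
  treated - control
}

#' Residue class of an amyloid-beta(1-42) position
#'
#' Classes: aromatic (Phe, Tyr; aromatic takes precedence over
#' hydrophobic), hydrophobic (Ala, Val, Leu, Ile, Met), charged (Asp,
#' Glu, Arg, Lys), polar (Ser, Thr, Asn, Gln, His), other (Gly).
#'
#' @param position Residue number(s), 1-42.
#' @return Character vector of classes.
#' @export
#' @examples
#' classify_residue(19) # "aromatic" (Phe19)
classify_residue <- function(position) {
  if (any(position < 1 | position > 42)) {
    stop("position out of range 1..42")
  }
  one <- ab42_sequence("one")[position]
  cls <- rep("other", length(one))
  cls[one %in% c("F", "Y")] <- "aromatic"
  cls[one %in% c("A", "V", "L", "I", "M")] <- "hydrophobic"
  cls[one %in% c("D", "E", "R", "K")] <- "charged"
  cls[one %in% c("S", "T", "N", "Q", "H")] <- "polar"
  cls[one %in% c("F", "Y")] <- "aromatic"  # precedence over hydrophobic
  cls
}

#' Ordinary least-squares fit of ddG against solvent-accessibility change
#'
#' @param ddg Per-residue ddG values.
#' @param dsasa Per-residue solvent-accessibility changes (same length,
#'   n >= 3).
#' @return List with `slope`, `intercept`, `r_squared`, `p_value`.
#' @export
ddg_sasa_correlation <- function(ddg, dsasa) {
  stopifnot(length(ddg) == length(dsasa), length(ddg) >= 3)
  if (stats::var(dsasa) == 0) stop("zero variance in predictor")
  fit <- stats::lm(ddg ~ dsasa)
  s <- summary(fit)
  list(slope = unname(stats::coef(fit)[2]),
       intercept = unname(stats::coef(fit)[1]),
       r_squared = s$r.squared,
       p_value = unname(s$coefficients[2, 4]))
}

#' Long-format class-annotated ddG table for group comparisons
#'
#' @param ddg Matrix from [ddg_matrix()] (residues x windows).
#' @return data.frame with columns `resid`, `window`, `ddg`, `class`.
#' @export
ddg_long_table <- function(ddg) {
  resid <- as.integer(rownames(ddg))
  out <- data.frame(
    resid = rep(resid, ncol(ddg)),
    window = rep(colnames(ddg), each = nrow(ddg)),
    ddg = as.numeric(ddg))
  out$class <- classify_residue(out$resid)
  out[!is.na(out$ddg), ]
}
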