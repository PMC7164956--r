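#' @title Reflection sets
#' @description A reflection set is a data.frame of unique Miller indices with
#'   an amplitude column `f` (electrons; signed for difference coefficients),
#'   optional `sigf`, `phi` (degrees) and `weight` columns, plus a
#'   [unit_cell()] and a free-text label carried as attributes.
#' @name reflection_set
NULL

#' Construct a reflection set
#'
#' @param h,k,l Integer Miller indices.
#' @param f Amplitudes in electrons (signed values allowed for difference
#'   coefficients).
#' @param sigf,phi,weight Optional sigmas (electrons), phases (degrees in
#'   \[-180, 180)) and weights.
#' @param cell A [unit_cell()].
#' @param label Free-text label, e.g. `"Fo_light"`.
#' @return Object of class `refl_set` (a data.frame).
#' @export
reflection_set <- function(h, k, l, f, sigf = NA_real_, phi = NA_real_,
                           weight = NA_real_, cell, label = "") {
  df <- data.frame(h = as.integer(h), k = as.integer(k), l = as.integer(l),
                   f = as.numeric(f), sigf = as.numeric(sigf),
                   phi = as.numeric(phi), weight = as.numeric(weight))
  if (anyDuplicated(df[c("h", "k", "l")])) stop("duplicate (h,k,l) indices")
  if (any(df$sigf < 0, na.rm = TRUE)) stop("sigmas must be >= 0")
  df$phi <- wrap_phase(df$phi)
  attr(df, "cell") <- cell
  attr(df, "label") <- label
  class(df) <- c("refl_set", "data.frame")
  df
}

wrap_phase <- function(phi) {
  out <- ((phi + 180) %% 360) - 180
  out
}

refl_cell <- function(rs) attr(rs, "cell")
refl_label <- function(rs) attr(rs, "label")

#' Resolution of every reflection in a set
#' @param rs A `refl_set`.
#' @return d-spacings in angstrom.
#' @export
refl_d <- function(rs) d_spacing(refl_cell(rs), rs$h, rs$k, rs$l)

# complex structure factors from (possibly signed) amplitude + phase
refl_complex <- function(rs) {
  if (any(is.na(rs$phi))) stop("reflection set has ", sum(is.na(rs$phi)),
                               " missing phase(s)")
  rs$f * exp(1i * pi * rs$phi / 180)
}

hkl_key <- function(df) paste(df$h, df$k, df$l)

# inner join of reflection sets on (h,k,l); returns list of row indices
match_hkl <- function(a, b) {
  ia <- match(hkl_key(b), hkl_key(a))
  keep <- !is.na(ia)
  list(a = ia[keep], b = which(keep))
}

#' Write a reflection set as tab-separated text
#'
#' Columns `h k l F sigF phi weight` with empty fields for absent values; a
#' `# cell` comment line preserves the unit cell so files round-trip.
#'
#' @param rs A `refl_set`.
#' @param path Output path.
#' @export
write_reflections <- function(rs, path) {
  cl <- refl_cell(rs)
  hdr <- c(
    sprintf("# cell %.6g %.6g %.6g %.6g %.6g %.6g", cl$a, cl$b, cl$c,
            cl$alpha, cl$beta, cl$gamma),
    sprintf("# label %s", refl_label(rs)),
    paste(c("h", "k", "l", "F", "sigF", "phi", "weight"), collapse = "\t")
  )
  body <- sprintf("%d\t%d\t%d\t%s\t%s\t%s\t%s", rs$h, rs$k, rs$l,
                  fmt_num(rs$f), fmt_num(rs$sigf), fmt_num(rs$phi),
                  fmt_num(rs$weight))
  writeLines(c(hdr, body), path)
}

fmt_num <- function(x) ifelse(is.na(x), "", sprintf("%.10g", x))

#' Read a reflection set written by [write_reflections()]
#'
#' @param path Input path.
#' @param cell Optional [unit_cell()]; taken from the `# cell` header if absent.
#' @return A `refl_set`.
#' @export
read_reflections <- function(path, cell = NULL) {
  lines <- readLines(path, warn = FALSE)
  label <- ""
  for (ln in lines[startsWith(lines, "#")]) {
    if (startsWith(ln, "# cell ")) {
      v <- as.numeric(strsplit(trimws(sub("# cell", "", ln)), "\\s+")[[1]])
      cell <- unit_cell(v[1], v[2], v[3], v[4], v[5], v[6])
    } else if (startsWith(ln, "# label ")) {
      label <- trimws(sub("# label", "", ln))
    }
  }
  if (is.null(cell)) stop("no cell in file header and none supplied")
  tab <- utils::read.delim(textConnection(lines[!startsWith(lines, "#")]),
                           na.strings = c("", "NA"))
  reflection_set(tab$h, tab$k, tab$l, tab$F, tab$sigF, tab$phi, tab$weight,
                 cell = cell, label = label)
}
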