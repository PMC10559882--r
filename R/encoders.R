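#' Biological time sequence container
#'
#' @param values Numeric vector (one channel) or matrix with one column per
#'   channel (CGR has two: x and y coordinates).
#' @param encoding One of `"spectral"`, `"cgr"`, `"z"` (or `"series"` for
#'   plain numeric series).
#' @param source_id Label of the originating sequence.
#' @param normalization Provenance tag; `"none"` straight out of an encoder.
#' @return An object of class `bts`.
#' @export
bts <- function(values, encoding = "series", source_id = "",
                normalization = "none") {
  if (!is.numeric(values)) stop_arg("`values` must be numeric")
  structure(list(values = values, encoding = encoding, source_id = source_id,
                 normalization = normalization), class = "bts")
}

#' @export
print.bts <- function(x, ...) {
  len <- if (is.matrix(x$values)) nrow(x$values) else length(x$values)
  ch <- if (is.matrix(x$values)) ncol(x$values) else 1L
  cat(sprintf("<bts> encoding=%s source=%s n=%d channels=%d norm=%s\n",
              x$encoding, x$source_id, len, ch, x$normalization))
  invisible(x)
}

# Accept a dna_seq or a plain string; return uppercase character vector.
seq_chars <- function(seq) {
  if (inherits(seq, "dna_seq")) {
    if (seq$n == 0L) stop_arg("sequence '%s' is empty", seq$id)
    strsplit(seq$bases, "", fixed = TRUE)[[1]]
  } else if (is.character(seq) && length(seq) == 1L) {
    if (nchar(seq) == 0L) stop_arg("sequence is empty")
    strsplit(toupper(seq), "", fixed = TRUE)[[1]]
  } else {
    stop_arg("`seq` must be a dna_seq or a single character string")
  }
}

seq_label <- function(seq) if (inherits(seq, "dna_seq")) seq$id else ""

#' Spectral encoding of a DNA sequence
#'
#' Maps residues directly to integers: a -> 1, g -> 2, c -> 3, t -> 4.
#' The mapping is invertible (see [decode_spectral()]).
#'
#' @param seq A [dna_seq] or character string.
#' @return A one-channel [bts] with values in \{1, 2, 3, 4\}.
#' @examples
#' encode_spectral("AGCT")$values  # 1 2 3 4
#' @export
encode_spectral <- function(seq) {
  chars <- seq_chars(seq)
  code <- c(A = 1, G = 2, C = 3, T = 4)
  bts(unname(code[chars]), "spectral", seq_label(seq))
}

#' Invert the spectral encoding
#' @param x A spectral [bts] or numeric vector of values in \{1,2,3,4\}.
#' @param id Identifier of the reconstructed sequence.
#' @return A [dna_seq].
#' @export
decode_spectral <- function(x, id = "decoded") {
  v <- if (inherits(x, "bts")) x$values else x
  if (!all(v %in% 1:4)) stop_arg("spectral values must be in {1,2,3,4}")
  dna_seq(id, paste(c("A", "G", "C", "T")[v], collapse = ""))
}

#' Default CGR vertex assignment
#'
#' Corners of the unit square assigned to the four bases:
#' A = (1, 1), C = (-1, -1), G = (-1, 1), T = (1, -1).
#'
#' @return A 4x2 numeric matrix with rownames A, C, G, T.
#' @export
cgr_default_vertices <- function() {
  m <- rbind(A = c(1, 1), C = c(-1, -1), G = c(-1, 1), T = c(1, -1))
  colnames(m) <- c("x", "y")
  m
}

#' Chaos game representation of a DNA sequence
#'
#' Iterative midpoint mapping: starting from the origin, each base moves the
#' point half-way toward that base's corner of the square \[-1, 1\]^2:
#' CGR_i = CGR_(i-1) - (CGR_(i-1) - g_i) / 2. Every point lies strictly
#' inside the square and successive points contract toward the current
#' corner by exactly one half.
#'
#' @param seq A [dna_seq] or character string.
#' @param vertices 4x2 matrix of corner coordinates (rownames A, C, G, T);
#'   rows must be distinct corners of the square.
#' @return A two-channel [bts] (columns x, y), one row per base.
#' @export
encode_cgr <- function(seq, vertices = cgr_default_vertices()) {
  chars <- seq_chars(seq)
  vertices <- as.matrix(vertices)
  if (!all(c("A", "C", "G", "T") %in% rownames(vertices)) ||
      ncol(vertices) != 2L) {
    stop_arg("`vertices` must be a 4x2 matrix with rownames A, C, G, T")
  }
  if (anyDuplicated(vertices[c("A", "C", "G", "T"), , drop = FALSE])) {
    stop_arg("CGR corners must be distinct")
  }
  corners <- vertices[chars, , drop = FALSE]
  n <- length(chars)
  # CGR_i = (CGR_{i-1} + g_i)/2  =>  CGR_n = sum_i g_i / 2^{n-i+1}
  out <- matrix(0, n, 2L, dimnames = list(NULL, c("x", "y")))
  prev <- c(0, 0)
  for (i in seq_len(n)) {
    prev <- prev - (prev - corners[i, ]) / 2
    out[i, ] <- prev
  }
  bts(out, "cgr", seq_label(seq))
}

#' Collapse a two-channel CGR series to one channel
#'
#' The CGR trajectory is a sequence of 2-vectors; a scalar projection is
#' needed to use it as a single time series. Default is the Euclidean norm
#' (symmetric in both coordinates); `"x"`/`"y"` select one coordinate.
#'
#' @param series2d A two-channel [bts] (or 2-column matrix).
#' @param mode `"norm"`, `"x"` or `"y"`.
#' @return A one-channel [bts].
#' @export
cgr_scalar <- function(series2d, mode = c("norm", "x", "y")) {
  mode <- match.arg(mode)
  v <- if (inherits(series2d, "bts")) series2d$values else series2d
  if (!is.matrix(v) || ncol(v) != 2L) {
    stop_arg("`series2d` must have exactly 2 channels")
  }
  out <- switch(mode,
    norm = sqrt(v[, 1]^2 + v[, 2]^2),
    x = v[, 1],
    y = v[, 2]
  )
  src <- if (inherits(series2d, "bts")) series2d$source_id else ""
  bts(unname(out), "cgr", src)
}

#' Z-curve cumulative components of a DNA sequence
#'
#' For each prefix of length i, with A_i, C_i, G_i, T_i the cumulative base
#' counts: X_i = (A_i + G_i) - (C_i + T_i) (purine/pyrimidine disparity),
#' Y_i = (A_i + C_i) - (G_i + T_i) (amino/keto), Z_i = (A_i + T_i) -
#' (C_i + G_i) (weak/strong). Identity: X_i + Y_i + Z_i = 4 A_i - i.
#'
#' @param seq A [dna_seq] or character string.
#' @return A list with integer vectors `A`, `C`, `G`, `T`, `X`, `Y`, `Z`.
#' @export
z_components <- function(seq) {
  chars <- seq_chars(seq)
  A <- cumsum(chars == "A"); C <- cumsum(chars == "C")
  G <- cumsum(chars == "G"); T <- cumsum(chars == "T")
  list(A = A, C = C, G = G, T = T,
       X = (A + G) - (C + T), Y = (A + C) - (G + T), Z = (A + T) - (C + G))
}

#' Z-curve encoding of a DNA sequence
#'
#' The scalar series is the square root of X_i + Y_i + Z_i = 4 A_i - i.
#' That sum is negative whenever the A-content of the prefix is below 25%,
#' so the plain real square root is undefined there; the default policy is
#' the signed root sign(v) * sqrt(|v|), which preserves the disparity's sign
#' and monotone information. `"clamp"` maps negative sums to 0 instead.
#'
#' @param seq A [dna_seq] or character string.
#' @param negative `"signed_sqrt"` (default) or `"clamp"`.
#' @return A one-channel [bts].
#' @export
encode_z <- function(seq, negative = c("signed_sqrt", "clamp")) {
  negative <- match.arg(negative)
  comp <- z_components(seq)
  s <- comp$X + comp$Y + comp$Z
  vals <- if (negative == "signed_sqrt") sign(s) * sqrt(abs(s)) else sqrt(pmax(s, 0))
  bts(vals, "z", seq_label(seq))
}

#' Export an encoded series to CSV
#'
#' One-channel series use the two-column (index, value) layout; two-channel
#' CGR uses three columns (index, x, y).
#'
#' @param x A [bts].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bts_csv <- function(x, path) {
  stopifnot(inherits(x, "bts"))
  if (is.matrix(x$values)) {
    df <- data.frame(index = seq_len(nrow(x$values)),
                     x = x$values[, 1], y = x$values[, 2])
  } else {
    df <- data.frame(index = seq_along(x$values), value = x$values)
  }
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
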