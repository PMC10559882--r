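#' DNA sequence object
#'
#' Light container for a validated DNA sequence: an identifier and a string of
#' canonical uppercase residues (A, C, G, T).
#'
#' @param id Character label for the sequence.
#' @param bases Character scalar of residues; lower case is canonicalized to
#'   upper case. Only A/C/G/T are accepted here; ambiguity codes are resolved
#'   at read time (see [read_fasta()]).
#' @return An object of class `dna_seq` with fields `id`, `bases`, `n`.
#' @examples
#' dna_seq("x", "ACGT")
#' @export
dna_seq <- function(id, bases) {
  stopifnot(is.character(id), length(id) == 1L)
  stopifnot(is.character(bases), length(bases) == 1L)
  bases <- toupper(bases)
  if (nchar(bases) > 0L) {
    chars <- strsplit(bases, "", fixed = TRUE)[[1]]
    bad <- which(!chars %in% c("A", "C", "G", "T"))
    if (length(bad) > 0L) {
      stop_arg("invalid residue '%s' at position %d in sequence '%s'",
               chars[bad[1]], bad[1], id)
    }
  }
  structure(list(id = id, bases = bases, n = nchar(bases)), class = "dna_seq")
}

#' @export
print.dna_seq <- function(x, ...) {
  preview <- if (x$n > 60) paste0(substr(x$bases, 1, 60), "...") else x$bases
  cat(sprintf("<dna_seq> %s (%d bp)\n%s\n", x$id, x$n, preview))
  invisible(x)
}

# IUPAC ambiguity codes and the canonical bases each is compatible with.
iupac_map <- list(
  N = c("A", "C", "G", "T"), R = c("A", "G"), Y = c("C", "T"),
  S = c("C", "G"), W = c("A", "T"), K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
  V = c("A", "C", "G")
)

#' Read DNA sequences from a FASTA file
#'
#' Records may be multi-line and upper or lower case; residues are
#' canonicalized to uppercase A/C/G/T. IUPAC ambiguity codes (N, R, Y, ...)
#' are resolved by the `ambiguity` policy: `"randomize"` (default) replaces
#' each with a canonical base drawn uniformly from the bases the code is
#' compatible with, using `seed`; `"strict"` rejects them.
#'
#' @param path Path to a FASTA file.
#' @param ambiguity Either `"randomize"` or `"strict"`.
#' @param seed Integer seed used by the `"randomize"` policy.
#' @return A list of [dna_seq] objects, in file order.
#' @export
read_fasta <- function(path, ambiguity = c("randomize", "strict"), seed = 1L) {
  ambiguity <- match.arg(ambiguity)
  if (!file.exists(path)) stop_arg("FASTA file not found: %s", path)
  first <- readLines(path, n = 1L, warn = FALSE)
  if (length(first) == 0L || !startsWith(first, ">")) {
    stop_arg("malformed FASTA: first line must be a '>' header in %s", path)
  }
  recs <- seqinr::read.fasta(path, seqtype = "DNA", forceDNAtolower = FALSE,
                             as.string = FALSE)
  with_seed(seed, {
    lapply(seq_along(recs), function(i) {
      chars <- toupper(as.character(recs[[i]]))
      id <- attr(recs[[i]], "name")
      bad <- which(!chars %in% c("A", "C", "G", "T", names(iupac_map)))
      if (length(bad) > 0L) {
        stop_arg("invalid residue '%s' at position %d in record '%s'",
                 chars[bad[1]], bad[1], id)
      }
      amb <- which(chars %in% names(iupac_map))
      if (length(amb) > 0L) {
        if (ambiguity == "strict") {
          stop_arg("ambiguity code '%s' at position %d in record '%s' (strict mode)",
                   chars[amb[1]], amb[1], id)
        }
        chars[amb] <- vapply(chars[amb], function(code) {
          opts <- iupac_map[[code]]
          opts[sample.int(length(opts), 1L)]
        }, character(1))
      }
      dna_seq(id, paste(chars, collapse = ""))
    })
  })
}

#' Write DNA sequences to a FASTA file
#'
#' Records are wrapped at 70 columns (conventional dialect).
#'
#' @param seqs A [dna_seq] or list of them.
#' @param path Output file path.
#' @param width Line width for wrapping.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path, width = 70L) {
  if (inherits(seqs, "dna_seq")) seqs <- list(seqs)
  seqinr::write.fasta(
    sequences = lapply(seqs, function(s) strsplit(s$bases, "")[[1]]),
    names = vapply(seqs, `[[`, character(1), "id"),
    file.out = path, nbchar = width
  )
  invisible(path)
}

#' Generate a synthetic DNA sequence
#'
#' Draws a sequence from either an i.i.d. model (`"uniform"`, with per-base
#' probabilities `base_probs`) or a first-order Markov chain (`"markov1"`,
#' with row-stochastic 4x4 `transition` over A, C, G, T). Identical arguments
#' and seed always reproduce the identical sequence.
#'
#' @param length Number of bases (>= 0).
#' @param model `"uniform"` or `"markov1"`.
#' @param base_probs Length-4 probability vector over A, C, G, T (uniform
#'   model; also the initial distribution of the Markov model).
#' @param transition 4x4 row-stochastic matrix (markov1 model).
#' @param seed Integer seed.
#' @param id Identifier of the returned sequence.
#' @return A [dna_seq].
#' @examples
#' generate_dna(20, seed = 7)
#' @export
generate_dna <- function(length, model = c("uniform", "markov1"),
                         base_probs = rep(0.25, 4), transition = NULL,
                         seed = 1L, id = "synthetic") {
  model <- match.arg(model)
  if (!is.numeric(length) || length < 0) stop_arg("`length` must be >= 0")
  length <- as.integer(length)
  bases <- c("A", "C", "G", "T")
  if (length(base_probs) != 4L || any(base_probs < 0) ||
      abs(sum(base_probs) - 1) > 1e-12) {
    stop_arg("`base_probs` must be 4 non-negative values summing to 1")
  }
  if (model == "markov1") {
    if (is.null(transition)) stop_arg("markov1 model requires `transition`")
    transition <- as.matrix(transition)
    if (!all(dim(transition) == c(4L, 4L)) || any(transition < 0) ||
        any(abs(rowSums(transition) - 1) > 1e-12)) {
      stop_arg("`transition` must be a 4x4 row-stochastic matrix")
    }
  }
  if (length == 0L) return(dna_seq(id, ""))
  out <- with_seed(seed, {
    if (model == "uniform") {
      sample(bases, length, replace = TRUE, prob = base_probs)
    } else {
      idx <- integer(length)
      idx[1] <- sample.int(4L, 1L, prob = base_probs)
      if (length > 1L) {
        u <- stats::runif(length - 1L)
        cum <- t(apply(transition, 1L, cumsum))
        for (i in 2:length) {
          idx[i] <- findInterval(u[i - 1L], cum[idx[i - 1L], ],
                                 left.open = TRUE) + 1L
        }
      }
      bases[idx]
    }
  })
  dna_seq(id, paste(out, collapse = ""))
}

#' Simulate an ARFIMA(p, d, q) series
#'
#' White noise is driven through the MA and AR filters (an ARMA(p, q)
#' process) and then fractionally integrated by order `d` with the truncated
#' binomial filter, so the true generating parameters are known exactly —
#' the basis of all parameter-recovery tests.
#'
#' @param n Number of points.
#' @param d Fractional integration order, |d| < 0.5.
#' @param ar,ma Numeric vectors of AR and MA coefficients (may be empty).
#' @param noise_sd Innovation standard deviation.
#' @param seed Integer seed.
#' @param mean Series mean added after integration.
#' @return Numeric vector of length `n`.
#' @export
generate_arfima_series <- function(n, d = 0, ar = numeric(0), ma = numeric(0),
                                   noise_sd = 1, seed = 1L, mean = 0) {
  if (!is.numeric(n) || n < 1) stop_arg("`n` must be >= 1")
  if (abs(d) >= 0.5) stop_arg("|d| must be < 0.5 (got %g)", d)
  if (length(ar) > 0 && any(Mod(polyroot(c(1, -ar))) <= 1)) {
    stop_arg("AR coefficients are not stationary")
  }
  n <- as.integer(n)
  x <- with_seed(seed, {
    if (length(ar) == 0 && length(ma) == 0) {
      stats::rnorm(n, sd = noise_sd)
    } else {
      as.numeric(stats::arima.sim(
        model = list(ar = ar, ma = ma), n = n, sd = noise_sd
      ))
    }
  })
  if (d != 0) x <- frac_integrate(x, d)
  x + mean
}

#' Write a numeric series to a two-column CSV (index, value)
#' @param x Numeric vector.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_series_csv <- function(x, path) {
  check_numeric_vector(x, "x", min_len = 0L)
  utils::write.csv(data.frame(index = seq_along(x), value = as.numeric(x)),
                   path, row.names = FALSE)
  invisible(path)
}

#' Read a numeric series from a two-column CSV written by [write_series_csv()]
#' @param path Input path.
#' @return Numeric vector.
#' @export
read_series_csv <- function(path) {
  if (!file.exists(path)) stop_arg("series file not found: %s", path)
  df <- utils::read.csv(path)
  if (!all(c("index", "value") %in% names(df))) {
    stop_arg("series CSV must have columns 'index' and 'value'")
  }
  as.numeric(df$value[order(df$index)])
}
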