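#' Describe one diffusion-weighted shell
#'
#' @param b b-value, s/mm^2
#' @param b_delta b-tensor shape in `[-1/2, 1]` (1 = LTE, 0 = STE)
#' @param n_dirs number of gradient directions (waveform rotations) acquired
#'   on this shell; the powder mean averages over them
#' @return one-row data.frame with columns `b`, `b_delta`, `n_dirs`
#' @export
shell <- function(b, b_delta, n_dirs) {
  stopifnot(b >= 0, b_delta >= -0.5, b_delta <= 1, n_dirs >= 1)
  data.frame(b = b, b_delta = b_delta, n_dirs = as.integer(n_dirs))
}

#' Assemble a measurement protocol
#'
#' A protocol is an ordered table of shells plus the echo time and the number
#' of b = 0 volumes. Shell order is meaningful: the estimator consumes powder
#' means in this order and records a fingerprint of it.
#'
#' @param shells data.frame with columns `b` (s/mm^2), `b_delta`, `n_dirs`,
#'   e.g. built by `rbind`-ing [shell()] rows
#' @param te_ms echo time, ms
#' @param n_b0 number of b = 0 volumes
#' @return object of class `soma_protocol`
#' @export
protocol <- function(shells, te_ms = 94, n_b0 = 12) {
  stopifnot(is.data.frame(shells), all(c("b", "b_delta", "n_dirs") %in% names(shells)))
  stopifnot(all(shells$b >= 0), all(shells$b_delta >= -0.5), all(shells$b_delta <= 1),
            all(shells$n_dirs >= 1), te_ms > 0, n_b0 >= 0)
  p <- list(shells = shells[, c("b", "b_delta", "n_dirs")],
            te_ms = te_ms, n_b0 = as.integer(n_b0))
  class(p) <- "soma_protocol"
  p$fingerprint <- protocol_fingerprint(p)
  p
}

#' The default LTE + STE protocol
#'
#' Four STE shells at b = 500/1000/1500/2000 s/mm^2 and four LTE shells at
#' b = 1000/2000/3500/5000 s/mm^2, with a fixed total direction budget per
#' encoding split across its four shells (equal split by default, remainder to
#' the highest shell), TE = 94 ms and 12 b = 0 volumes.
#'
#' @param n_dirs_total directions per encoding type (LTE and STE each),
#'   default 128
#' @param split optional length-4 integer vector of per-shell direction counts
#'   (applied to both encodings); overrides the equal split
#' @return a `soma_protocol`
#' @export
default_protocol <- function(n_dirs_total = 128, split = NULL) {
  if (is.null(split)) {
    base <- n_dirs_total %/% 4
    split <- rep(base, 4)
    split[4] <- split[4] + n_dirs_total - sum(split)
  }
  stopifnot(length(split) == 4L, all(split >= 1))
  ste <- data.frame(b = c(500, 1000, 1500, 2000), b_delta = 0, n_dirs = as.integer(split))
  lte <- data.frame(b = c(1000, 2000, 3500, 5000), b_delta = 1, n_dirs = as.integer(split))
  protocol(rbind(ste, lte), te_ms = 94, n_b0 = 12)
}

#' Fingerprint of a protocol
#'
#' Canonical string over the ordered (b, b_delta, n_dirs) triples and the echo
#' time. An estimator trained on a protocol stores this fingerprint and
#' refuses signal vectors from a different protocol, because the mapping from
#' powder means to parameters is protocol-specific.
#'
#' @param p a `soma_protocol`
#' @return character scalar
#' @export
protocol_fingerprint <- function(p) {
  stopifnot(inherits(p, "soma_protocol"))
  sh <- p$shells
  paste0("v1|te=", sprintf("%.3f", as.numeric(p$te_ms)), "|",
         paste(sprintf("%g:%g:%d", sh$b, sh$b_delta, sh$n_dirs), collapse = ";"))
}

## Compatibility fingerprint: b-values, shapes, TE and the *relative*
## direction split. Powder means are direction-count-invariant inputs, so an
## estimator transfers to a protocol that differs only in the total direction
## budget, provided the per-measurement noise level is rescaled to keep the
## powder-mean noise consistent (see estimate_params).
compat_fingerprint <- function(p) {
  sh <- p$shells
  share <- sh$n_dirs / sum(sh$n_dirs)
  paste0("v1c|te=", sprintf("%.3f", as.numeric(p$te_ms)), "|",
         paste(sprintf("%g:%g:%.6f", sh$b, sh$b_delta, share), collapse = ";"))
}

#' @export
print.soma_protocol <- function(x, ...) {
  cat("B-tensor protocol:", nrow(x$shells), "shells, TE =", x$te_ms, "ms,",
      x$n_b0, "b0 volumes\n")
  print(x$shells, row.names = FALSE)
  invisible(x)
}

#' Deterministic quasi-uniform unit vectors on the sphere
#'
#' Spherical Fibonacci lattice; deterministic and close to uniform, used to
#' rotate waveforms across directions within a shell.
#'
#' @param n number of directions
#' @return n x 3 matrix of unit vectors
#' @export
fibonacci_directions <- function(n) {
  stopifnot(n >= 1)
  i <- seq_len(n) - 0.5
  phi <- pi * (1 + sqrt(5)) * i
  z <- 1 - 2 * i / n
  r <- sqrt(pmax(0, 1 - z^2))
  cbind(r * cos(phi), r * sin(phi), z)
}

#' Expand a protocol into a per-volume scheme table
#'
#' One row per acquired volume: b = 0 rows first, then each shell's directions
#' from a Fibonacci lattice.
#'
#' @param p a `soma_protocol`
#' @return data.frame with columns `b` (s/mm^2), `b_delta`, `nx`, `ny`, `nz`
#' @export
scheme_from_protocol <- function(p) {
  stopifnot(inherits(p, "soma_protocol"))
  rows <- list()
  if (p$n_b0 > 0) {
    rows[[1]] <- data.frame(b = 0, b_delta = 0,
                            nx = 0, ny = 0, nz = rep(1, p$n_b0))
  }
  for (k in seq_len(nrow(p$shells))) {
    sh <- p$shells[k, ]
    d <- fibonacci_directions(sh$n_dirs)
    rows[[length(rows) + 1L]] <- data.frame(b = sh$b, b_delta = sh$b_delta,
                                            nx = d[, 1], ny = d[, 2], nz = d[, 3])
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Read / write plain-text scheme files
#'
#' One row per volume with columns `b` (s/mm^2), `b_delta`, `nx`, `ny`, `nz`
#' and header line `# b bdelta nx ny nz`.
#'
#' @param path file path
#' @return `read_scheme`: data.frame with the five columns
#' @export
read_scheme <- function(path) {
  tab <- utils::read.table(path, header = FALSE, comment.char = "#",
                           col.names = c("b", "b_delta", "nx", "ny", "nz"))
  stopifnot(all(tab$b >= 0))
  tab
}

#' @rdname read_scheme
#' @param scheme data.frame as returned by [scheme_from_protocol()]
#' @export
write_scheme <- function(scheme, path) {
  stopifnot(all(c("b", "b_delta", "nx", "ny", "nz") %in% names(scheme)))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("# b bdelta nx ny nz", con)
  utils::write.table(format(scheme[, c("b", "b_delta", "nx", "ny", "nz")],
                            digits = 10, trim = TRUE),
                     con, row.names = FALSE, col.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Infer a protocol from a scheme table
#'
#' Groups non-zero-b rows into shells by unique (b, b_delta) in order of first
#' appearance and counts directions per shell.
#'
#' @param scheme data.frame from [read_scheme()]
#' @param te_ms echo time, ms (not recorded in scheme files)
#' @return a `soma_protocol`
#' @export
protocol_from_scheme <- function(scheme, te_ms = 94) {
  dw <- scheme[scheme$b > 0, ]
  key <- paste(dw$b, dw$b_delta)
  first <- !duplicated(key)
  shells <- data.frame(b = dw$b[first], b_delta = dw$b_delta[first],
                       n_dirs = as.integer(table(key)[unique(key)]))
  protocol(shells, te_ms = te_ms, n_b0 = sum(scheme$b == 0))
}

#' Read / write protocol JSON
#'
#' Format: `{"shells":[{"b":..., "bdelta":..., "ndirs":...}], "te_ms":...,
#' "nb0":...}` with b in s/mm^2.
#'
#' @param path file path
#' @export
read_protocol_json <- function(path) {
  j <- jsonlite::fromJSON(path)
  shells <- data.frame(b = j$shells$b, b_delta = j$shells$bdelta,
                       n_dirs = as.integer(j$shells$ndirs))
  protocol(shells, te_ms = j$te_ms, n_b0 = j$nb0)
}

#' @rdname read_protocol_json
#' @param p a `soma_protocol`
#' @export
write_protocol_json <- function(p, path) {
  stopifnot(inherits(p, "soma_protocol"))
  obj <- list(shells = data.frame(b = p$shells$b, bdelta = p$shells$b_delta,
                                  ndirs = p$shells$n_dirs),
              te_ms = p$te_ms, nb0 = p$n_b0)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
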