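#' Diffusion gradient tables
#'
#' A gradient table pairs b-values (s/mm^2) with unit gradient directions and
#' defines the diffusion acquisition scheme. At least one b = 0 entry and at
#' least six diffusion-weighted directions spanning 3-space are required for a
#' tensor fit.
#'
#' @param bvals numeric vector of non-negative b-values in s/mm^2.
#' @param bvecs numeric matrix with one row per entry and 3 columns; rows with
#'   bval > 0 must have (approximately) unit norm and are renormalized.
#' @return an object of class `gradient_table` with elements `bvals` (length K)
#'   and `bvecs` (K x 3).
#' @export
gradient_table <- function(bvals, bvecs) {
  bvals <- as.numeric(bvals)
  bvecs <- as.matrix(bvecs)
  if (nrow(bvecs) != length(bvals) || ncol(bvecs) != 3) {
    stop_validation("'bvecs' must be a K x 3 matrix matching length(bvals)")
  }
  if (any(!is.finite(bvals)) || any(bvals < 0)) {
    stop_validation("b-values must be finite and non-negative")
  }
  dw <- bvals > 0
  nrm <- sqrt(rowSums(bvecs^2))
  if (any(dw & nrm < 1e-8)) {
    stop_validation("zero direction vector for a diffusion-weighted entry")
  }
  bvecs[dw, ] <- bvecs[dw, , drop = FALSE] / nrm[dw]
  bvecs[!dw, ] <- 0
  dimnames(bvecs) <- NULL
  if (sum(!dw) < 1) stop_validation("gradient table needs at least one b = 0 entry")
  if (sum(dw) < 6) stop_validation("gradient table needs at least 6 diffusion-weighted directions")
  structure(list(bvals = bvals, bvecs = bvecs), class = "gradient_table")
}

#' @export
print.gradient_table <- function(x, ...) {
  cat(sprintf("gradient_table: %d entries (%d b=0, %d weighted), b in [%g, %g] s/mm^2\n",
              length(x$bvals), sum(x$bvals == 0), sum(x$bvals > 0),
              min(x$bvals), max(x$bvals)))
  invisible(x)
}

#' Default 15-direction acquisition scheme
#'
#' Emulates the study acquisition: 15 approximately uniformly distributed,
#' pairwise noncollinear unit directions at b = 800 s/mm^2, preceded by one
#' unweighted (b = 0) entry. Directions are a deterministic spherical Fibonacci
#' set on the upper hemisphere (antipodal directions are equivalent in
#' diffusion MRI).
#'
#' @param n_directions number of diffusion-weighted directions (default 15).
#' @param bvalue diffusion weighting in s/mm^2 (default 800).
#' @return a [gradient_table()] with `n_directions + 1` entries.
#' @export
default_gradient_table <- function(n_directions = 15, bvalue = 800) {
  check_positive(n_directions, "n_directions", 1)
  check_positive(bvalue, "bvalue", 1)
  n <- as.integer(n_directions)
  i <- seq_len(n) - 0.5
  golden <- pi * (3 - sqrt(5))
  # hemisphere Fibonacci lattice: z in (0, 1), azimuth by the golden angle
  z <- i / n
  r <- sqrt(pmax(0, 1 - z^2))
  theta <- golden * (seq_len(n) - 1)
  dirs <- cbind(r * cos(theta), r * sin(theta), z)
  gradient_table(c(0, rep(bvalue, n)), rbind(c(0, 0, 0), dirs))
}

#' Read FSL-dialect bval/bvec files
#'
#' `bval` is one whitespace-separated row of K b-values; `bvec` is three rows
#' of K components (x, y, z).
#'
#' @param bval_path,bvec_path file paths.
#' @return a [gradient_table()].
#' @export
read_gradients <- function(bval_path, bvec_path) {
  if (!file.exists(bval_path)) stop_parse(paste("missing bval file:", bval_path))
  if (!file.exists(bvec_path)) stop_parse(paste("missing bvec file:", bvec_path))
  bvals <- scan(bval_path, quiet = TRUE)
  bv <- as.matrix(read.table(bvec_path))
  if (nrow(bv) != 3) stop_parse(sprintf("bvec file '%s' must have 3 rows, found %d", bvec_path, nrow(bv)))
  if (ncol(bv) != length(bvals)) {
    stop_validation(sprintf("bval/bvec length mismatch: %d b-values vs %d directions",
                            length(bvals), ncol(bv)))
  }
  gradient_table(bvals, t(bv))
}

#' Write FSL-dialect bval/bvec files
#'
#' @param gradients a [gradient_table()].
#' @param bval_path,bvec_path output paths.
#' @return invisibly, the two paths.
#' @export
write_gradients <- function(gradients, bval_path, bvec_path) {
  stopifnot(inherits(gradients, "gradient_table"))
  writeLines(paste(format(gradients$bvals, scientific = FALSE, trim = TRUE),
                   collapse = " "), bval_path)
  write.table(t(gradients$bvecs), bvec_path, row.names = FALSE,
              col.names = FALSE)
  invisible(c(bval_path, bvec_path))
}
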