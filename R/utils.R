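#' @keywords internal
"_PACKAGE"

#' @importFrom stats cor dnorm predict qnorm rnorm runif sd var
#' @importFrom utils head read.csv read.table write.csv write.table
NULL

abort_iscn <- function(msg, class) {
  stop(structure(
    class = c(class, "iscn_error", "error", "condition"),
    list(message = msg, call = sys.call(-1))
  ))
}

stop_validation <- function(msg) abort_iscn(msg, "iscn_validation_error")
stop_config <- function(msg) abort_iscn(msg, "iscn_config_error")
stop_parse <- function(msg) abort_iscn(msg, "iscn_parse_error")

#' Evaluate code under a temporary RNG seed
#'
#' Runs `code` with the global random generator seeded to `seed` and restores
#' the previous generator state afterwards, so that package functions are pure
#' functions of their inputs and never perturb the caller's RNG stream.
#'
#' @param seed single integer seed.
#' @param code expression to evaluate.
#' @return the value of `code`.
#' @keywords internal
with_seed <- function(seed, code) {
  had_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had_seed) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(code)
}

# scalar checks used by the spec constructors
check_positive <- function(x, name, n = length(x)) {
  if (length(x) != n || !is.numeric(x) || any(!is.finite(x)) || any(x <= 0)) {
    stop_validation(sprintf("'%s' must be %d positive finite number(s)", name, n))
  }
  invisible(x)
}

check_flag <- function(x, name) {
  if (!is.logical(x) || length(x) != 1L || is.na(x)) {
    stop_validation(sprintf("'%s' must be TRUE or FALSE", name))
  }
  invisible(x)
}

# upper-triangle (i < j) edge index in lexicographic (i, then j) order
edge_index_pairs <- function(n_regions) {
  if (n_regions < 2) {
    return(matrix(integer(0), ncol = 2,
                  dimnames = list(NULL, c("region_i", "region_j"))))
  }
  idx <- which(upper.tri(matrix(0, n_regions, n_regions)), arr.ind = TRUE)
  idx <- idx[order(idx[, 1], idx[, 2]), , drop = FALSE]
  colnames(idx) <- c("region_i", "region_j")
  idx
}
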