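#' @importFrom rlang %||% abort warn .data
#' @importFrom tibble tibble as_tibble
#' @importFrom dplyr mutate filter select arrange group_by ungroup summarise
#'   left_join n_distinct bind_rows across all_of
#' @importFrom stats median mad quantile qnorm rnorm rgamma var sd setNames
#'   lm optimize dgamma integrate coef resid acf
NULL

# Canonical species key: trim, collapse whitespace runs to "_", lowercase.
# Newick tip labels conventionally use underscores where tables use spaces.
canonicalize_species <- function(x) {
  x <- gsub("[[:space:]]+", "_", trimws(as.character(x)))
  tolower(x)
}

# Deterministic child seeds below 2^31, derived from one master seed.
derive_seeds <- function(seed, n) {
  old <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(as.integer(seed))
  sample.int(.Machine$integer.max - 1L, n)
}

# Cholesky with a documented jitter fallback: if V is numerically singular,
# 1e-10 is added to the diagonal (once) and the event is messaged.
chol_psd <- function(V, jitter = 1e-10) {
  out <- tryCatch(chol(V), error = function(e) NULL)
  if (is.null(out)) {
    message("Cholesky failed; retrying with diagonal jitter ", jitter)
    out <- chol(V + diag(jitter, nrow(V)))
  }
  out
}

# Matrix square-root factor F with F %*% t(F) = V, valid for PSD V
# (zero eigenvalues allowed, unlike chol()).
psd_factor <- function(V, tol = 1e-8) {
  eg <- eigen((V + t(V)) / 2, symmetric = TRUE)
  if (min(eg$values) < -tol * max(abs(eg$values), 1)) {
    abort("matrix is not positive semi-definite", class = "phyloyawn_domain_error")
  }
  eg$vectors %*% diag(sqrt(pmax(eg$values, 0)), nrow(V))
}

stop_domain <- function(msg) abort(msg, class = "phyloyawn_domain_error")
stop_format <- function(msg) abort(msg, class = "phyloyawn_format_error")

logmeanexp <- function(x) {
  m <- max(x)
  m + log(mean(exp(x - m)))
}
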