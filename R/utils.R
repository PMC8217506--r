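#' @useDynLib vascufem, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats rnorm runif qlnorm plnorm pnorm lm coef cor pt quantile sd var complete.cases
#' @importFrom utils write.csv read.csv
NULL

# run code with a private RNG stream so package functions never disturb the
# caller's random state
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      old <- get(".Random.seed", envir = globalenv())
      on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
    } else {
      on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
              add = TRUE)
    }
    set.seed(as.integer(seed))
  }
  force(code)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stopifnot_scalar <- function(x, name = deparse(substitute(x))) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    stop(sprintf("`%s` must be a finite numeric scalar", name), call. = FALSE)
  }
  invisible(x)
}

rownorms <- function(m) sqrt(rowSums(m * m))

normalize_rows <- function(m) {
  n <- rownorms(m)
  n[n == 0] <- 1
  m / n
}

# Rodrigues rotation of row vectors `v` about unit row vectors `axis`
rotate_rows <- function(v, axis, theta) {
  ct <- cos(theta)
  st <- sin(theta)
  crossp <- cbind(axis[, 2] * v[, 3] - axis[, 3] * v[, 2],
                  axis[, 3] * v[, 1] - axis[, 1] * v[, 3],
                  axis[, 1] * v[, 2] - axis[, 2] * v[, 1])
  dotp <- rowSums(axis * v)
  v * ct + crossp * st + axis * dotp * (1 - ct)
}

# symmetric 3x3 tensor <-> length-6 Voigt-ordered vector (xx,yy,zz,xy,yz,xz)
sym_to_vec6 <- function(a) c(a[1, 1], a[2, 2], a[3, 3], a[1, 2], a[2, 3], a[1, 3])

vec6_to_sym <- function(v) {
  matrix(c(v[1], v[4], v[6],
           v[4], v[2], v[5],
           v[6], v[5], v[3]), 3, 3)
}
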