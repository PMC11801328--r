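#' Acquisition schemes for combined diffusion-relaxation MRI
#'
#' An acquisition scheme is an ordered table of measurements, one row per
#' acquired volume, with columns `b` (diffusion weighting, s/mm^2),
#' `gx`, `gy`, `gz` (unit gradient direction; arbitrary for b = 0) and
#' `te` (echo time, ms). The attribute `te_min` caches the shortest echo
#' time, the reference point for all T2* decay terms.
#'
#' @param b numeric vector of b-values, s/mm^2 (>= 0).
#' @param directions numeric matrix with one row per measurement and columns
#'   (x, y, z); rows with b > 0 must have unit norm.
#' @param te numeric vector of echo times, ms (> 0).
#' @return A data frame of class `acq_scheme` with attribute `te_min`.
#' @examples
#' s <- acq_scheme(b = c(0, 800), directions = rbind(c(1, 0, 0), c(0, 1, 0)),
#'                 te = c(78, 78))
#' te_min(s)
#' @export
acq_scheme <- function(b, directions, te) {
  directions <- matrix(as.numeric(directions), ncol = 3)
  b <- as.numeric(b)
  te <- as.numeric(te)
  n <- length(b)
  if (n == 0L)
    stop("an acquisition scheme must contain at least one measurement")
  if (nrow(directions) != n || length(te) != n)
    stop("b, directions and te must describe the same number of measurements")
  scheme <- data.frame(b = b, gx = directions[, 1], gy = directions[, 2],
                       gz = directions[, 3], te = te)
  class(scheme) <- c("acq_scheme", "data.frame")
  validate_scheme(scheme)
  attr(scheme, "te_min") <- min(scheme$te)
  scheme
}

#' @rdname acq_scheme
#' @param scheme an `acq_scheme`.
#' @export
te_min <- function(scheme) {
  tm <- attr(scheme, "te_min")
  if (is.null(tm)) tm <- min(scheme$te)
  tm
}

validate_scheme <- function(scheme) {
  if (nrow(scheme) == 0L)
    stop("an acquisition scheme must contain at least one measurement")
  if (any(scheme$b < 0)) stop("b-values must be non-negative")
  if (any(scheme$te <= 0)) stop("echo times must be positive")
  norms <- sqrt(scheme$gx^2 + scheme$gy^2 + scheme$gz^2)
  bad <- scheme$b > 0 & abs(norms - 1) > 1e-6
  if (any(bad))
    stop(sprintf("gradient directions must be unit vectors for b > 0 (%d offending rows, first at row %d)",
                 sum(bad), which(bad)[1]))
  invisible(scheme)
}

# Shell layout of the placental protocol: direction count per b-value.
paper_shells <- function() {
  b <- c(5, 10, 18, 25, 36, 50, 100, 200, 400, 600, 800, 1200, 1600)
  n <- c(3, 3, 8, 3, 7, 3, 3, 3, 3, 3, 15, 3, 3)
  data.frame(b = b, n_dir = n)
}

paper_echo_times <- function() c(78, 114, 150, 186)

#' Evenly spread unit directions on the sphere
#'
#' Generates `n` gradient directions by electrostatic-repulsion descent:
#' points are initialised from a seeded uniform draw on the sphere and
#' iteratively pushed apart under an antipodally symmetric Coulomb-type
#' energy (diffusion directions are sign-invariant), then renormalised.
#' Deterministic for a given `(n, seed)`.
#'
#' @param n number of directions.
#' @param seed integer seed for the initial draw.
#' @param n_iter descent iterations.
#' @return an `n` x 3 matrix of unit row vectors.
#' @export
sphere_directions <- function(n, seed = 1L, n_iter = 200L) {
  stopifnot(n >= 1)
  p <- with_local_seed(seed, {
    m <- matrix(stats::rnorm(3 * n), ncol = 3)
    m / sqrt(rowSums(m^2))
  })
  if (n == 1L) return(matrix(p, ncol = 3))
  step <- 0.05
  for (iter in seq_len(n_iter)) {
    force <- matrix(0, n, 3)
    for (i in seq_len(n)) {
      d1 <- sweep(p, 2, p[i, ])          # p - p_i
      d2 <- sweep(-p, 2, p[i, ])         # antipodes
      r1 <- rowSums(d1^2); r2 <- rowSums(d2^2)
      r1[i] <- Inf; r2[r2 < 1e-12] <- Inf
      force[i, ] <- -colSums(d1 / (r1^1.5 + 1e-12)) - colSums(d2 / (r2^1.5 + 1e-12))
    }
    p <- p + step * force / max(1, max(abs(force)))
    p <- p / sqrt(rowSums(p^2))
  }
  p
}

#' Build the placental multi-echo multi-b acquisition scheme
#'
#' Constructs the full measurement table of the protocol: three gradient
#' directions at each of b = 5, 10, 25, 50, 100, 200, 400, 600, 1200 and
#' 1600 s/mm^2, eight at b = 18, seven at b = 36 and fifteen at b = 800,
#' every diffusion preparation repeated at echo times 78, 114, 150 and
#' 186 ms (60 preparations, 240 measurements, TE_min = 78 ms). Only the
#' per-shell direction counts are protocol-defined; the direction
#' coordinates themselves come from [sphere_directions()] with a fixed
#' seed so the scheme is reproducible. Ordering is shells ascending in b,
#' directions in generation order, echo time innermost.
#'
#' @return an [acq_scheme()].
#' @examples
#' s <- build_paper_scheme()
#' nrow(s)                       # 240
#' sum(s$b == 800 & s$te == 78)  # 15
#' @export
build_paper_scheme <- function() {
  shells <- paper_shells()
  tes <- paper_echo_times()
  rows <- vector("list", nrow(shells))
  for (k in seq_len(nrow(shells))) {
    nd <- shells$n_dir[k]
    dirs <- sphere_directions(nd, seed = 1000L + k)
    idx <- rep(seq_len(nd), each = length(tes))
    rows[[k]] <- data.frame(b = shells$b[k],
                            gx = dirs[idx, 1], gy = dirs[idx, 2],
                            gz = dirs[idx, 3],
                            te = rep(tes, times = nd))
  }
  tab <- do.call(rbind, rows)
  acq_scheme(tab$b, cbind(tab$gx, tab$gy, tab$gz), tab$te)
}

#' Read and write scheme sidecar files
#'
#' The on-disk dialect is the FSL convention: a `bval` file (one
#' space-separated row of b-values), a `bvec` file (three rows: x, y, z
#' components) and an equally long echo-time file in ms. Values are
#' written with 6 significant digits, enough for a lossless round trip at
#' that precision.
#'
#' @param bval_path,bvec_path,te_path sidecar file paths.
#' @return `read_scheme` returns an [acq_scheme()]; `write_scheme`
#'   invisibly returns the three paths.
#' @export
read_scheme <- function(bval_path, bvec_path, te_path) {
  bval <- read_numeric_rows(bval_path, n_rows = 1)
  bvec <- read_numeric_rows(bvec_path, n_rows = 3)
  te <- read_numeric_rows(te_path, n_rows = 1)
  n <- length(bval[[1]])
  if (length(unique(lengths(bvec))) != 1L || lengths(bvec)[1] != n)
    stop(sprintf("length mismatch: '%s' has %d entries but '%s' rows have %s",
                 bval_path, n, bvec_path,
                 paste(unique(lengths(bvec)), collapse = "/")))
  if (length(te[[1]]) != n)
    stop(sprintf("length mismatch: '%s' has %d entries but '%s' has %d",
                 bval_path, n, te_path, length(te[[1]])))
  acq_scheme(bval[[1]], cbind(bvec[[1]], bvec[[2]], bvec[[3]]), te[[1]])
}

read_numeric_rows <- function(path, n_rows) {
  if (!file.exists(path)) stop(sprintf("sidecar file '%s' not found", path))
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) != n_rows)
    stop(sprintf("'%s': expected %d non-empty rows, found %d",
                 path, n_rows, length(lines)))
  lapply(seq_along(lines), function(i) {
    tok <- strsplit(trimws(lines[i]), "[[:space:]]+")[[1]]
    val <- suppressWarnings(as.numeric(tok))
    if (anyNA(val))
      stop(sprintf("'%s' line %d: non-numeric token '%s'",
                   path, i, tok[which(is.na(val))[1]]))
    val
  })
}

#' @rdname read_scheme
#' @param scheme an [acq_scheme()].
#' @export
write_scheme <- function(scheme, bval_path, bvec_path, te_path) {
  validate_scheme(scheme)
  fmt <- function(x) paste(signif(x, 6), collapse = " ")
  writeLines(fmt(scheme$b), bval_path)
  writeLines(c(fmt(scheme$gx), fmt(scheme$gy), fmt(scheme$gz)), bvec_path)
  writeLines(fmt(scheme$te), te_path)
  invisible(c(bval_path, bvec_path, te_path))
}

#' Restrict a scheme to its shortest echo time
#'
#' FA is estimated from the diffusion data at the first (shortest) echo
#' time only; this helper extracts that subset.
#'
#' @param scheme an [acq_scheme()].
#' @return the sub-scheme at `te == te_min(scheme)`, with measurement
#'   indices in attribute `index`.
#' @export
scheme_at_te_min <- function(scheme) {
  idx <- which(scheme$te == te_min(scheme))
  out <- acq_scheme(scheme$b[idx],
                    cbind(scheme$gx, scheme$gy, scheme$gz)[idx, , drop = FALSE],
                    scheme$te[idx])
  attr(out, "index") <- idx
  out
}
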