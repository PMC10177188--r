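## internal helpers shared across modules

## evaluate expr with a temporary RNG state seeded by `seed`; NULL seed uses
## (and advances) the current stream
.withSeed <- function(seed, expr) {
    if (is.null(seed)) return(force(expr))
    has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    if (has) old <- get(".Random.seed", envir = globalenv())
    on.exit({
        if (has) assign(".Random.seed", old, envir = globalenv())
        else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
            rm(".Random.seed", envir = globalenv())
    })
    set.seed(seed)
    force(expr)
}

## standard normal truncated to [-3, 3], by inverse-CDF so a single uniform
## maps monotonically to the deviate (keeps comonotone coupling simple)
.truncStdNorm <- function(n) {
    lo <- stats::pnorm(-3)
    hi <- stats::pnorm(3)
    stats::qnorm(stats::runif(n, lo, hi))
}

## Wilson 95% score interval for a binomial proportion
.wilson <- function(k, n, conf = 0.95) {
    z <- stats::qnorm(1 - (1 - conf) / 2)
    p <- k / n
    den <- 1 + z^2 / n
    ctr <- (p + z^2 / (2 * n)) / den
    hw <- z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2)) / den
    c(max(0, ctr - hw), min(1, ctr + hw))
}

## separable 3-point (boxcar) mean along one axis of a 3D array, edge pixels
## handled by 1-sample reflective padding (edge value repeated)
.box3Axis <- function(a, axis) {
    n <- dim(a)[axis]
    if (n < 3L) stop("volume must be at least 3 px in each axis")
    lo <- c(1L, seq_len(n - 1L))
    hi <- c(seq_len(n - 1L) + 1L, n)
    if (axis == 1L)      (a[lo, , , drop = FALSE] + a + a[hi, , , drop = FALSE]) / 3
    else if (axis == 2L) (a[, lo, , drop = FALSE] + a + a[, hi, , drop = FALSE]) / 3
    else                 (a[, , lo, drop = FALSE] + a + a[, , hi, drop = FALSE]) / 3
}

## 3x3x3 local mean of a 3D array
.box27 <- function(a) .box3Axis(.box3Axis(.box3Axis(a, 1L), 2L), 3L)

## reverse cumulative sum *below* each row of a (nz x L) matrix:
## out[i, ] = colSums(m[(i+1):nz, ]); out[nz, ] = 0
.sumBelow <- function(m) {
    nz <- nrow(m)
    out <- m * 0
    for (i in (nz - 1L):1L) out[i, ] <- out[i + 1L, ] + m[i + 1L, ]
    out
}

## 2D median filter (k x k, k odd) with edge replication; NA centers stay NA,
## NA neighbours are ignored
.medianFilter2D <- function(m, k = 5L) {
    if (k <= 1L) return(m)
    r <- (k - 1L) %/% 2L
    nx <- nrow(m); ny <- ncol(m)
    stack <- array(NA_real_, c(nx, ny, k * k))
    s <- 0L
    for (dx in -r:r) for (dy in -r:r) {
        s <- s + 1L
        xi <- pmin(pmax(seq_len(nx) + dx, 1L), nx)
        yi <- pmin(pmax(seq_len(ny) + dy, 1L), ny)
        stack[, , s] <- m[xi, yi]
    }
    out <- apply(stack, c(1, 2), stats::median, na.rm = TRUE)
    out[is.na(m)] <- NA_real_
    out[is.nan(out)] <- NA_real_
    out
}

.jsonWrite <- function(x, path) {
    jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
}

.stopIfMissing <- function(path, what) {
    if (!file.exists(path))
        stop(sprintf("missing %s: '%s' does not exist", what, path),
             call. = FALSE)
    invisible(path)
}
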