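# Small internal utilities.

# Evaluate expr under a temporary RNG state seeded with `seed`, restoring the
# caller's RNG afterwards. All stochastic operations in the package funnel
# their draws through this so results are reproducible per (input, seed).
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
          rm(".Random.seed", envir = globalenv())
        }
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    }, add = TRUE)
    set.seed(seed)
  }
  expr
}

# Derive a child seed from a parent seed and an index, staying within the
# 32-bit integer range R requires of set.seed().
child_seed <- function(seed, i) {
  (as.numeric(seed) * 7919 + as.numeric(i) * 104729) %% 2147483647
}

runif1 <- function(lo, hi) stats::runif(1, lo, hi)

`%||%` <- function(a, b) if (is.null(a)) b else a

# Rotate 2-column point matrix by angle (degrees) about origin.
rotate_points <- function(pts, angle_deg) {
  th <- angle_deg * pi / 180
  R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
  pts %*% t(R)
}

# MD5 of an arbitrary R object via its serialization (version-pinned so the
# hash is stable across sessions).
object_hash <- function(x) {
  f <- tempfile()
  on.exit(unlink(f))
  con <- file(f, "wb")
  serialize(x, con, version = 2)
  close(con)
  unname(tools::md5sum(f))
}
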