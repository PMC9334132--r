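# Shared fixtures: the template is expensive enough to build once per run.

.fixtures <- new.env(parent = emptyenv())

test_template <- function() {
  if (is.null(.fixtures$tpl)) .fixtures$tpl <- make_template()
  .fixtures$tpl
}

# construct a perf_zmap directly from an array (unit tests of clustering)
zmap_from_array <- function(vals, include = NULL, spacing = c(2, 2, 2)) {
  if (is.null(include)) include <- array(TRUE, dim(vals))
  d1 <- dim(vals)[1L]
  structure(list(values = vals, include = include,
                 mean_used = 0, sd_used = 1, sd_type = "population",
                 grid = grid_spec(dim(vals), spacing,
                                  -(dim(vals) - 1) / 2 * spacing),
                 mid_index = if (d1 %% 2L == 1L) (d1 + 1L) / 2L else NA_real_),
            class = "perf_zmap")
}

# independent flood-fill oracle for connected components (slow, simple):
# repeated boundary dilation of a single seed, one component at a time
oracle_label_components <- function(mask, connectivity) {
  d <- dim(mask)
  off <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  off <- off[rowSums(abs(off)) > 0, , drop = FALSE]
  off <- switch(as.character(connectivity),
                "6" = off[rowSums(abs(off)) == 1, , drop = FALSE],
                "18" = off[rowSums(abs(off)) <= 2, , drop = FALSE],
                "26" = off)
  lab <- array(0L, d)
  nlab <- 0L
  idx <- which(mask)
  for (s in idx) {
    if (lab[s] > 0L) next
    nlab <- nlab + 1L
    queue <- s
    lab[s] <- nlab
    while (length(queue)) {
      v <- queue[[1L]]
      queue <- queue[-1L]
      v0 <- v - 1L
      i <- v0 %% d[1L] + 1L
      j <- (v0 %/% d[1L]) %% d[2L] + 1L
      k <- v0 %/% (d[1L] * d[2L]) + 1L
      for (o in seq_len(nrow(off))) {
        ni <- i + off[o, 1L]; nj <- j + off[o, 2L]; nk <- k + off[o, 3L]
        if (ni < 1L || ni > d[1L] || nj < 1L || nj > d[2L] ||
            nk < 1L || nk > d[3L]) next
        nv <- ni + d[1L] * ((nj - 1L) + d[2L] * (nk - 1L))
        if (mask[nv] && lab[nv] == 0L) {
          lab[nv] <- nlab
          queue <- c(queue, nv)
        }
      }
    }
  }
  list(labels = lab, n = nlab)
}

# place a small spherical blob of given value into an array, in mm coords
add_blob <- function(vals, template, center, radius, value) {
  m <- (template$coords$x - center[1])^2 + (template$coords$y - center[2])^2 +
    (template$coords$z - center[3])^2 <= radius^2
  vals[m] <- value
  vals
}

blob_mask <- function(template, center, radius) {
  (template$coords$x - center[1])^2 + (template$coords$y - center[2])^2 +
    (template$coords$z - center[3])^2 <= radius^2
}
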