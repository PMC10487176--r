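# Small phantom used by the unit tests: same voxel sizes as the default
# study, quarter-sized grids so each stage runs in well under a second.
small_spec <- function(...) {
  defaults <- list(
    ct_dim = c(48, 48, 48), mr_dim = c(32, 32, 32),
    bone_center = c(5, 6.55, 5), cap_radius = c(5, 4, 4.5),
    shaft_radius = 2.5, shaft_length = 7, shell = 1.2, phi_smooth = 2,
    insert_x = 11.4, insert_radius = 0.8
  )
  do.call(phantom_spec, utils::modifyList(defaults, list(...)))
}

# brute-force median filter over the truncated spherical neighbourhood;
# independent of the compiled implementation
median_oracle <- function(vals, radius) {
  d <- dim(vals)
  out <- array(0, d)
  offs <- expand.grid(a = -radius:radius, b = -radius:radius, c = -radius:radius)
  offs <- offs[offs$a^2 + offs$b^2 + offs$c^2 <= radius^2, ]
  for (i in 1:d[1]) for (j in 1:d[2]) for (k in 1:d[3]) {
    ii <- i + offs$a; jj <- j + offs$b; kk <- k + offs$c
    ok <- ii >= 1 & ii <= d[1] & jj >= 1 & jj <= d[2] & kk >= 1 & kk <= d[3]
    out[i, j, k] <- median(vals[cbind(ii[ok], jj[ok], kk[ok])])
  }
  out
}

# flood-fill connected components, plain R BFS; returns a label array
flood_fill_oracle <- function(mask, connectivity = 26) {
  d <- dim(mask)
  offs <- expand.grid(a = -1:1, b = -1:1, c = -1:1)
  s <- abs(offs$a) + abs(offs$b) + abs(offs$c)
  offs <- offs[s > 0 & s <= switch(as.character(connectivity),
                                   "6" = 1, "18" = 2, "26" = 3), ]
  labels <- array(0L, d)
  nxt <- 0L
  for (start in which(mask & labels == 0L)) {
    if (labels[start] != 0L) next
    nxt <- nxt + 1L
    queue <- start
    labels[start] <- nxt
    while (length(queue)) {
      cur <- queue[1]; queue <- queue[-1]
      i <- (cur - 1) %% d[1] + 1
      j <- ((cur - 1) %/% d[1]) %% d[2] + 1
      k <- (cur - 1) %/% (d[1] * d[2]) + 1
      ii <- i + offs$a; jj <- j + offs$b; kk <- k + offs$c
      ok <- ii >= 1 & ii <= d[1] & jj >= 1 & jj <= d[2] & kk >= 1 & kk <= d[3]
      lin <- ii[ok] + (jj[ok] - 1) * d[1] + (kk[ok] - 1) * d[1] * d[2]
      hit <- lin[mask[lin] & labels[lin] == 0L]
      labels[hit] <- nxt
      queue <- c(queue, hit)
    }
  }
  labels
}

random_grid <- function(d = c(8, 8, 8), seed = 1, spacing = c(1, 1, 1)) {
  set.seed(seed)
  voxel_grid(array(rnorm(prod(d)), d), spacing = spacing)
}
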