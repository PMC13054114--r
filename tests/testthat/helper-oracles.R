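# Independent brute-force oracles and tiny fixture builders. These stay
# deliberately naive (O(N*K) scans, BFS labelling) so they cannot share a
# defect with the implementation they check.

# Exhaustive nearest-foreground-pixel Euclidean distance, in pixel units
brute_force_edt <- function(mask) {
  idx <- which(mask, arr.ind = TRUE)
  stopifnot(nrow(idx) > 0)
  out <- matrix(NA_real_, nrow(mask), ncol(mask))
  for (r in seq_len(nrow(mask))) {
    for (c in seq_len(ncol(mask))) {
      out[r, c] <- sqrt(min((idx[, 1] - r)^2 + (idx[, 2] - c)^2))
    }
  }
  out
}

# 4-connected component areas by breadth-first search
brute_force_component_areas <- function(mask) {
  seen <- matrix(FALSE, nrow(mask), ncol(mask))
  areas <- integer(0)
  for (start in which(mask & !seen)) {
    if (seen[start]) next
    queue <- start
    seen[start] <- TRUE
    size <- 0L
    while (length(queue)) {
      cur <- queue[1]; queue <- queue[-1]
      size <- size + 1L
      r <- (cur - 1L) %% nrow(mask) + 1L
      c <- (cur - 1L) %/% nrow(mask) + 1L
      for (d in list(c(-1L, 0L), c(1L, 0L), c(0L, -1L), c(0L, 1L))) {
        r2 <- r + d[1]; c2 <- c + d[2]
        if (r2 >= 1 && r2 <= nrow(mask) && c2 >= 1 && c2 <= ncol(mask)) {
          j <- (c2 - 1L) * nrow(mask) + r2
          if (mask[j] && !seen[j]) {
            seen[j] <- TRUE
            queue <- c(queue, j)
          }
        }
      }
    }
    areas <- c(areas, size)
  }
  areas
}

# Filled digital disk; half = 0.5 treats a pixel as a unit square (centre
# within radius + 0.5), half = 0 keeps the digital area near pi * r^2
draw_disk <- function(shape, cy, cx, radius, half = 0.5) {
  rr <- matrix(seq_len(shape[1]), shape[1], shape[2])
  cc <- matrix(seq_len(shape[2]), shape[1], shape[2], byrow = TRUE)
  (rr - cy)^2 + (cc - cx)^2 <= (radius + half)^2
}

# Independent arithmetic chain for the plasmid count: sphere volume ->
# dry mass -> pDNA share on the albumin basis -> molecules via Avogadro
oracle_plasmids <- function(d_nm, rho, w, L_bp, m_bp) {
  NA_const <- 6.02214076e23
  V <- (pi / 6) * (d_nm * 1e-7)^3
  m <- rho * V
  m_dna <- m * w / (1 + w)
  m_dna * NA_const / (L_bp * m_bp)
}

# Minimal three-channel scene built from explicit masks, noise-free
scene_from_masks <- function(nuclei, cells, particles,
                             pixel_size_um = 0.15537, meta = list()) {
  bg <- function(m, lo, hi) {
    img <- matrix(lo, nrow(m), ncol(m))
    img[m] <- hi
    img
  }
  scene(list(nuclei = bg(nuclei, 10, 200),
             cell = bg(cells, 10, 140),
             particle = bg(particles, 5, 150)),
        pixel_size_um = pixel_size_um, meta = meta)
}
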