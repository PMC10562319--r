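# brute-force geometric-overlap resampling oracle: rectangle intersection of
# every (coarse, fine) cell pair, independent of the matrix implementation
brute_force_resample <- function(fine_mask, fine_size, coarse_size) {
  nrf <- nrow(fine_mask); ncf <- ncol(fine_mask)
  nrc <- ceiling(nrf * fine_size / coarse_size)
  ncc <- ceiling(ncf * fine_size / coarse_size)
  out <- matrix(0, nrc, ncc)
  for (I in seq_len(nrc)) for (J in seq_len(ncc)) {
    clo_r <- (I - 1) * coarse_size; chi_r <- I * coarse_size
    clo_c <- (J - 1) * coarse_size; chi_c <- J * coarse_size
    acc <- 0
    for (i in seq_len(nrf)) for (j in seq_len(ncf)) {
      if (fine_mask[i, j] == 0) next
      ov_r <- max(0, min(chi_r, i * fine_size) - max(clo_r, (i - 1) * fine_size))
      ov_c <- max(0, min(chi_c, j * fine_size) - max(clo_c, (j - 1) * fine_size))
      acc <- acc + ov_r * ov_c * fine_mask[i, j]
    }
    out[I, J] <- acc / coarse_size^2
  }
  out
}

# minimal 2x2 single-region landscape grid for aggregation tests
tiny_grid <- function() {
  landscape_grid(
    category = matrix(c("forest", "forest", "arable", "wetland"), 2),
    subcategory = matrix(c("mineral_soil", "drained_peatland",
                           "organic_annual", "mire_class_2"), 2),
    region = matrix(1L, 2, 2),
    cell_size = 250)
}
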