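# shared fixture builders (all synthetic, generated at test time)

noise_free_optics <- function(...) {
  args <- utils::modifyList(
    list(shot_noise = FALSE, read_noise_sd = 0, background_level = 0,
         camera_offset = 0),
    list(...))
  do.call(optics_model, args)
}

default_noisy_optics <- function(...) {
  optics_model(...)
}

square_cell <- function(side_um = 20) {
  rbind(c(0, 0), c(side_um, 0), c(side_um, side_um), c(0, side_um))
}

disc_cell <- function(r_um = 10, centre = c(10, 10), n_vertices = 128) {
  th <- seq(0, 2 * pi, length.out = n_vertices + 1)[-(n_vertices + 1)]
  cbind(centre[1] + r_um * cos(th), centre[2] + r_um * sin(th))
}

# brute-force minimum assignment cost by permutation enumeration
brute_force_assignment_cost <- function(C) {
  n <- nrow(C)
  perms <- function(v) {
    if (length(v) == 1) return(list(v))
    out <- list()
    for (i in seq_along(v)) {
      for (p in perms(v[-i])) out[[length(out) + 1]] <- c(v[i], p)
    }
    out
  }
  min(vapply(perms(seq_len(n)),
             function(p) sum(C[cbind(seq_len(n), p)]), numeric(1)))
}

# MSD curve of one track at the given lags
track_msd <- function(tr, lags) {
  n <- nrow(tr)
  vapply(lags, function(L) {
    a <- seq_len(n - L)
    mean((tr$x_um[a + L] - tr$x_um[a])^2 + (tr$y_um[a + L] - tr$y_um[a])^2)
  }, numeric(1))
}
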