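# Brute-force oracles shared across test files.  Each is written
# independently of the implementation it checks: direct loops, no shared
# helpers from the package internals.

# occupancy by direct per-filament bookkeeping over the raw event rows
brute_occupancy <- function(events, footprint_nt, lattice_nt, t) {
  keep <- events$time_min <= t
  ev <- events[keep, , drop = FALSE]
  fil <- list()   # id -> c(start, protomers)
  for (r in seq_len(nrow(ev))) {
    id <- as.character(ev$filament_id[r])
    if (ev$kind[r] == "nucleate") {
      fil[[id]] <- c(ev$position_nt[r], ev$protomer_count[r])
    } else if (ev$kind[r] == "add") {
      f <- fil[[id]]
      if (ev$end[r] == "5p") f[1] <- f[1] - footprint_nt
      f[2] <- f[2] + 1
      fil[[id]] <- f
    } else if (ev$kind[r] == "burst") {
      f <- fil[[id]]
      f[2] <- f[2] - ev$protomer_count[r]
      if (ev$end[r] == "5p") f[1] <- f[1] + ev$protomer_count[r] * footprint_nt
      fil[[id]] <- if (f[2] > 0) f else NULL
    }
  }
  if (length(fil) == 0) return(0)
  covered <- rep(FALSE, lattice_nt)
  for (f in fil) {
    idx <- seq.int(f[1] + 1, f[1] + f[2] * footprint_nt)
    covered[idx] <- TRUE
  }
  mean(covered)
}

# maximal runs of TRUE in a logical vector: list of c(start, length)
brute_runs <- function(v) {
  out <- list()
  i <- 1L
  while (i <= length(v)) {
    if (v[i]) {
      j <- i
      while (j < length(v) && v[j + 1L]) j <- j + 1L
      out[[length(out) + 1L]] <- c(i, j - i + 1L)
      i <- j + 1L
    } else i <- i + 1L
  }
  out
}

# sliding-window median with reflect padding, direct loop
brute_median_filter <- function(x, width) {
  if (width %% 2L == 0L) width <- width + 1L
  half <- width %/% 2L
  n <- length(x)
  xp <- c(x[half:1], x, x[n:(n - half + 1L)])
  vapply(seq_len(n), function(i) median(xp[i:(i + 2L * half)]), numeric(1))
}

# non-overlapping block means, trailing partial block dropped
brute_block_means <- function(x, block) {
  m <- length(x) %/% block
  vapply(seq_len(m), function(i) mean(x[((i - 1L) * block + 1L):(i * block)]),
         numeric(1))
}

# a random noiseless staircase with resolvable segments
random_staircase <- function(n, n_steps, min_seg = 3L, step_range = c(1, 3)) {
  repeat {
    cps <- sort(sample(min_seg:(n - min_seg), n_steps))
    if (n_steps == 0L || all(diff(c(0L, cps, n)) >= min_seg)) break
  }
  lev <- cumsum(c(runif(1, -5, 5),
                  sample(c(-1, 1), n_steps, replace = TRUE) *
                    runif(n_steps, step_range[1], step_range[2])))
  list(x = rep(lev, diff(c(0L, cps, n))), cps = as.integer(cps))
}

# small fast simulation configs used in several files
quick_static_log <- function(starts, protomers, lattice = 10000L,
                             duration = 5, seed = 1) {
  cfg <- sim_config(lattice_length_nt = lattice, nucleation_rate_const_J = 0,
                    add_rate_5p = 0, add_rate_3p = 0, off_attempt_rate = 0,
                    duration_min = duration, seed = seed)
  simulate_assembly(cfg, initial_filaments = data.frame(
    start_nt = starts, protomers = protomers))
}
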