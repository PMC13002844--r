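# shared fixtures, all generated in code

std_montage <- montage_64_1020()
canon <- make_canonical_templates(std_montage)

# wrap a channels x frames matrix as a single kept epoch
as_epochs <- function(m, fs = 1000, montage = NULL, reference = "average") {
  structure(list(data = array(m, c(nrow(m), ncol(m), 1L)), fs = fs,
                 montage = montage, epoch_s = ncol(m) / fs,
                 kept = TRUE, reason = "", reference = reference),
            class = "ms_epochs")
}

# short synthetic subject: planted sequence + noiseless or noisy recording
quick_subject <- function(seed, length_s = 10, fs = 1000, snr = 10,
                          mean_dur = c(A = 60, B = 60, C = 80, D = 60)) {
  dyn <- dynamics_spec(mean_dur, snr = snr)
  sq <- simulate_state_sequence(dyn, length_s, fs, seed = seed)
  rec <- synthesize_recording(canon, sq, seed = seed + 1L)
  list(dyn = dyn, seq = sq, rec = rec)
}

# all permutations of a small vector, for exhaustive matching oracles
all_perms <- function(v) {
  if (length(v) <= 1L) return(list(v))
  out <- list()
  for (i in seq_along(v)) {
    for (p in all_perms(v[-i])) out[[length(out) + 1L]] <- c(v[i], p)
  }
  out
}
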