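# Build a one-row audiogram set from flat threshold vectors.
# air: 7 values over 125-8000 Hz; bone: 5 values over 250-4000 Hz.
make_audiogram <- function(air, bone, id = "s1", ear = "left", label = NULL) {
  audiogram_set(id, ear, ac = rbind(air), bc = rbind(bone), label = label)
}

# Flat audiogram: constant air level with a constant air-bone gap.
flat_audiogram <- function(air_level, gap = 0, id = "s1", ear = "left") {
  make_audiogram(rep(air_level, 7), rep(air_level - gap, 5), id = id,
                 ear = ear)
}

# Stack several one-row sets into one.
bind_audiograms <- function(...) {
  as_audiogram_set(do.call(rbind, lapply(list(...), as.data.frame)))
}

# A clean record passing all QC checks.
clean_audiogram <- function(id = "ok") flat_audiogram(20, gap = 5, id = id)
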