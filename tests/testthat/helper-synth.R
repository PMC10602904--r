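# Shared fixture builders. Everything is generated in code at test time;
# moderately expensive objects are cached for the session.

.fixture_env <- new.env(parent = emptyenv())

cached <- function(name, builder) {
  if (!exists(name, envir = .fixture_env)) {
    assign(name, builder(), envir = .fixture_env)
  }
  get(name, envir = .fixture_env)
}

# a small but complete cohort: 3 + 3 participants, 1 video, 250 Hz
small_cohort <- function() {
  cached("small_cohort", function() {
    spec <- synth_spec(n_group_a = 3, n_group_b = 3,
                       n_videos_per_condition = 1, eeg_rate_hz = 250,
                       seed = 42)
    make_cohort(spec)
  })
}

# feature matrix built from the small cohort on a coarse 8-bin grid
small_fm <- function() {
  cached("small_fm", function() {
    cohort <- small_cohort()
    grid <- frequency_grid(0.4, 3.2, 0.4)
    coh <- cohort_coherence(cohort, grid)
    keys <- paste(cohort$meta$participant, cohort$meta$condition, sep = "_")
    specs <- lapply(keys, function(k) {
      region_average(coh[paste(coh$participant, coh$condition,
                               sep = "_") == k, ])
    })
    assemble(specs, cohort$meta)
  })
}

# hand-built feature matrix with known structure (no signal processing)
toy_fm <- function(n_per_group = 8, n_feat_bins = 4, seed = 1,
                   effect = 0, effect_col = 1) {
  n <- n_per_group * 2
  inst <- expand.grid(condition = c("direct", "reversed"),
                      participant = sprintf("p%02d", seq_len(n)),
                      stringsAsFactors = FALSE)
  inst$group <- rep(c("a", "b"), each = n_per_group)[
    as.integer(sub("p", "", inst$participant))]
  inst <- inst[order(inst$group, inst$participant, inst$condition),
               c("participant", "group", "condition")]
  rownames(inst) <- NULL
  fn <- feature_names(seq(0.2, by = 0.2, length.out = n_feat_bins))
  vals <- withr::with_seed(seed,
    matrix(stats::rnorm(nrow(inst) * length(fn)), nrow(inst),
           dimnames = list(NULL, fn)))
  if (effect != 0) {
    hit <- inst$group == "a" & inst$condition == "direct"
    vals[hit, effect_col] <- vals[hit, effect_col] + effect
  }
  structure(list(values = vals, feature_names = fn, instances = inst,
                 scaling = NULL), class = "feature_matrix")
}
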