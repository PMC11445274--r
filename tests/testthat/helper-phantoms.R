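# Shared fixtures built in code. Heavyweight cohorts are computed once per
# test run and cached in this environment.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, builder) {
  if (is.null(.fixture_cache[[key]])) .fixture_cache[[key]] <- builder()
  .fixture_cache[[key]]
}

# small, fast phantom conditions for unit tests (not the study-analogue)
small_cohort_config <- function(n_patients = 2, seed = 1L, ...) {
  cohort_config(n_patients = n_patients,
                geometry = vox_geometry(c(32, 32, 32), c(2, 2, 2)),
                tumor_radius_mm = 10, rim_thickness_mm = 5,
                edema_margin_mm = 4, seed = seed, ...)
}

# the study-analogue cohort, processed end-to-end in memory (no file I/O)
default_processed_cohort <- function() {
  cached("default_processed", function() {
    cfg <- pipeline_config(out_dir = tempfile("unused"), seed = 1L,
                           cohort = default_cohort_config(seed = 1L))
    cases <- generate_cohort(cfg$cohort)
    channel_sets <- list(); svx_maps <- list(); svx_labels <- list()
    truth_agreement <- numeric(0)
    for (b in cases) {
      pr <- svxresp:::process_case(b, cfg)
      channel_sets[[b$case_id]] <- pr$channels
      svx_maps[[b$case_id]] <- pr$svx
      svx_labels[[b$case_id]] <- pr$majority
      truth_agreement <- c(truth_agreement,
                           mean((pr$labels$labels ==
                                   b$truth_labels$labels)[b$masks$cet]))
    }
    table <- extract_feature_table(cases, channel_sets, svx_maps, svx_labels)
    list(cases = cases, table = table, svx_maps = svx_maps,
         svx_labels = svx_labels, truth_agreement = truth_agreement)
  })
}

default_cv_result <- function() {
  cached("default_cv", function() {
    tab <- default_processed_cohort()$table
    cross_validate(tab, grouped_folds(tab, 10L, seed = 1L),
                   rf_config(seed = 1L))
  })
}

# cuboid mask with an attached geometry, for constructed examples
cuboid_mask <- function(shape = c(20, 10, 5), pad = 2,
                        spacing = c(1, 1, 1)) {
  g <- vox_geometry(shape + 2 * pad, spacing)
  m <- array(FALSE, dim = g$shape)
  m[pad + seq_len(shape[1]), pad + seq_len(shape[2]),
    pad + seq_len(shape[3])] <- TRUE
  as_volume(m, g)
}
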