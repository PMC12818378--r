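# Fixture builders: all test inputs are constructed in code.

make_records <- function(axon, myelin, sample_id = "S1", group = "CTL") {
  tibble::tibble(
    sample_id = rep_len(sample_id, length(axon)),
    group_label = rep_len(group, length(axon)),
    axon_diameter = axon,
    myelin_total = myelin,
    source_row = seq_along(axon) + 1L)
}

make_fibers <- function(axon, myelin, ...) {
  compute_fiber_and_g(make_records(axon, myelin, ...))
}

write_fixture_workbook <- function(cols, path = tempfile(fileext = ".xlsx")) {
  # cols: named list of vectors; NA cells written blank
  n <- max(vapply(cols, length, 1L))
  df <- tibble::as_tibble(lapply(cols, function(v) c(v, rep(NA, n - length(v)))))
  write_xlsx(list(Sheet1 = df), path)
  path
}

# Tiny deterministic generator settings for fast end-to-end tests
small_config <- function(seed = 7, n_baseline = 150, n_extreme = 15, ...) {
  sim_config(n_baseline = n_baseline, n_extreme = n_extreme, seed = seed, ...)
}
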