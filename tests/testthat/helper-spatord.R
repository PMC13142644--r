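# shared fixtures, built in code at test time

# hand-built two-cluster dataset for likelihood oracles
tiny_dataset <- function(y = c(0L, 1L), x = c(0, 0), K = 2L,
                         lon = c(0, 1), lat = c(0, 1)) {
  n <- length(y)
  structure(list(
    households = data.frame(household_id = seq_len(n),
                            cluster_id = seq_len(n),
                            lon = lon[seq_len(n)], lat = lat[seq_len(n)],
                            x = x, y = y),
    clusters = data.frame(cluster_id = seq_len(n), lon = lon[seq_len(n)],
                          lat = lat[seq_len(n)],
                          n_households = rep(1L, n)),
    design = "x", K = K,
    standardization = data.frame(name = character(), mean = numeric(),
                                 sd = numeric()),
    truth = NULL, surfaces = NULL, config = NULL),
    class = "survey_dataset")
}

# memoised medium-size correctly specified fit shared by the acceptance
# calibration / PPC / delta-SE checks
.fit_cache <- new.env(parent = emptyenv())

acceptance_fit <- function() {
  if (is.null(.fit_cache$fit)) {
    cfg <- survey_config(n_clusters = 200, households_per_cluster = c(25, 30),
                         seed = 2024L)
    dat <- simulate_survey(cfg)
    .fit_cache$config <- cfg
    .fit_cache$data <- dat
    .fit_cache$fit <- spatord(data = dat)
  }
  list(config = .fit_cache$config, data = .fit_cache$data,
       fit = .fit_cache$fit)
}
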