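#' Desk-scale synthetic benchmark
#'
#' The package's standard CPU-scale evaluation recipe: generate a synthetic
#' lateralized-EEG dataset (4-channel hand-area montage, 250 Hz, 4-s trials),
#' downsample to 125 Hz, build the three-band input and run an evaluation
#' scenario with the reduced model configuration and a short Adam schedule
#' (learning rate 1e-3, up to `max_epochs` epochs, early-stopping patience
#' `patience`). By default three of the ten within-session folds are trained,
#' which keeps a full run within a few minutes on one CPU; fold accuracies
#' are averaged as usual.
#'
#' @param erd_depth contralateral band-power attenuation of the generator.
#' @param seed root seed: generator, splits and per-fold training all derive
#'   from it.
#' @param folds_to_run which folds of the `k_folds`-fold split to train.
#' @param trials_per_session,n_sessions generator geometry (defaults: one
#'   200-trial session).
#' @param scenario evaluation scenario, see [make_splits()].
#' @param k_folds folds for CV scenarios.
#' @param max_epochs,patience,learning_rate,batch_size training schedule.
#' @return The [run_scenario()] result, with the generator config attached as
#'   attribute `synth_config`.
#' @export
desk_benchmark <- function(erd_depth = 0.8, seed = 0L, folds_to_run = 1:3,
                           trials_per_session = 200L, n_sessions = 1L,
                           scenario = "within_session", k_folds = 10L,
                           max_epochs = 20L, patience = 6L,
                           learning_rate = 1e-3, batch_size = 40L) {
  scfg <- synth_config(n_subjects = 1L, n_sessions = n_sessions,
                       trials_per_session = trials_per_session,
                       montage = reduced_motor_montage(),
                       erd_depth = erd_depth,
                       seed = derive_seed(seed, "synth"))
  ds <- generate_dataset(scfg)
  ep <- downsample(ds$epochs[[1L]], 125)
  mb <- make_multiband(ep)
  mcfg <- reduced_config(n_channels = n_channels(ep),
                         n_samples = n_samples(ep),
                         n_classes = scfg$n_classes)
  tcfg <- train_config(learning_rate = learning_rate,
                       max_epochs = max_epochs, batch_size = batch_size,
                       patience_epochs = patience,
                       seed = derive_seed(seed, "train"))
  res <- run_scenario(mb, ep, scenario, mcfg, tcfg, k_folds = k_folds,
                      seed = derive_seed(seed, "split"),
                      folds_to_run = folds_to_run)
  attr(res, "synth_config") <- scfg
  res
}
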