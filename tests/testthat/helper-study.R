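# The scaled-down comparative study is expensive (several network
# trainings), so it runs once per test session and is shared by the
# acceptance blocks that grade different aspects of it.

study_seed <- 1L

single_target_study <- function() {
  if (!is.null(.fixtures$study)) return(.fixtures$study)
  prof <- xclt_profile("desk")
  mesh <- build_mesh(50, prof$mesh_edge)
  ds <- generate_dataset(prof$n, study_seed * 1000L, mesh, prof$geometry,
                         prof$N, n_targets = 1L)
  sp <- split_dataset(ds, prof$split)
  gt <- lapply(sp$test, function(i) ds$images[i, , ])
  rep_fbp <- metric_report(gt, fbp_dataset(ds, sp$test))
  swin <- run_training(ds, "swin_cnn", prof$net, sp, prof$train,
                       seed = study_seed)
  rep_swin <- metric_report(gt, model_dataset(ds, swin, sp$test))
  am <- run_training(ds, "automap", prof$net, sp, prof$train,
                     seed = study_seed)
  rep_am <- metric_report(gt, model_dataset(ds, am, sp$test))
  .fixtures$study <- list(prof = prof, mesh = mesh, ds = ds, sp = sp,
                          fbp = rep_fbp$aggregate$mean,
                          swin = rep_swin$aggregate$mean,
                          automap = rep_am$aggregate$mean)
  .fixtures$study
}

resolution_study <- function() {
  if (!is.null(.fixtures$res_study)) return(.fixtures$res_study)
  prof <- xclt_profile("desk")
  mesh <- build_mesh(50, prof$mesh_edge)
  ds <- generate_dataset(prof$n, study_seed * 1000L + 500000L, mesh,
                         prof$geometry, prof$N, n_targets = "mixed12")
  sp <- split_dataset(ds, prof$split)
  n_res <- prof$split[3]
  res_ds <- generate_dataset(n_res, study_seed * 1000L + 600000L, mesh,
                             prof$geometry, prof$N,
                             separations = c(2, 4, 6, 8))
  gt <- lapply(seq_len(n_res), function(i) res_ds$images[i, , ])
  rep_fbp <- metric_report(gt, fbp_dataset(res_ds, seq_len(n_res)))
  swin <- run_training(ds, "swin_cnn", prof$net, sp, prof$train,
                       seed = study_seed)
  rep_swin <- metric_report(gt, model_dataset(res_ds, swin, seq_len(n_res)))
  .fixtures$res_study <- list(fbp = rep_fbp$aggregate$mean,
                              swin = rep_swin$aggregate$mean)
  .fixtures$res_study
}
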