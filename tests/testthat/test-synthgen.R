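test_that("generation is deterministic under the master seed", {
  cfg <- gen_config(n_proteins = 20, seed = 9)
  e1 <- gen_reference(cfg)
  e2 <- gen_reference(cfg)
  expect_identical(e1, e2)
  p1 <- gen_predictor(e1, -0.5, 0.5, 1, "m", seed = 9)
  p2 <- gen_predictor(e1, -0.5, 0.5, 1, "m", seed = 9)
  expect_identical(p1, p2)
  a1 <- gen_af2_series(e1, 1, seed = 9)
  a2 <- gen_af2_series(e1, 1, seed = 9)
  expect_identical(a1, a2)
  expect_false(identical(gen_reference(gen_config(n_proteins = 20, seed = 10)),
                         e1))
})

test_that("terminal-IDR probability zero keeps IDRs off the termini", {
  cfg <- gen_config(n_proteins = 300, p_terminus = 0,
                    length_meanlog = log(80), length_sdlog = 0.3,
                    mean_run_ordered = 500, mean_run_disordered = 10, seed = 3)
  entries <- gen_reference(cfg)
  first_disordered <- vapply(entries, function(e) e$disorder[1] == 1L, TRUE)
  expect_false(any(first_disordered))
})

test_that("run-length laws shape IDR lengths and prevalence", {
  long_cfg <- gen_config(n_proteins = 120, mean_run_disordered = 50,
                         mean_run_ordered = 100, length_meanlog = log(300),
                         seed = 5)
  short_cfg <- gen_config(n_proteins = 120, mean_run_disordered = 10,
                          mean_run_ordered = 100, length_meanlog = log(300),
                          seed = 5)
  med_len <- function(entries) {
    lens <- unlist(lapply(entries, function(e) extract_idrs(e$disorder)$length))
    median(lens)
  }
  expect_gt(med_len(gen_reference(long_cfg)), med_len(gen_reference(short_cfg)))

  # prevalence converges to the run-length-law value (within 2% at 1e5 residues)
  cfg <- gen_config(n_proteins = 300, length_meanlog = log(400),
                    length_sdlog = 0.3, mean_run_ordered = 120,
                    mean_run_disordered = 40, p_terminus = 40 / 160, seed = 8)
  entries <- gen_reference(cfg)
  labels <- unlist(lapply(entries, `[[`, "disorder"))
  expect_gt(length(labels), 1e5)
  expect_equal(mean(labels), 40 / 160, tolerance = 0.02 / (40 / 160))
})

test_that("binormal scores hit the closed-form AUC", {
  cfg <- gen_config(n_proteins = 250, length_meanlog = log(400),
                    length_sdlog = 0.3, seed = 12)
  entries <- gen_reference(cfg)
  labels <- unlist(lapply(entries, `[[`, "disorder"))
  expect_gt(length(labels), 1e5)

  prof <- gen_predictor(entries, 0, 1, 1, "sep1", seed = 12)
  scores <- unlist(lapply(prof, `[[`, "scores"))
  expect_equal(roc_auc(scores, labels), pnorm(1 / sqrt(2)), tolerance = 0.015)

  flat <- gen_predictor(entries, 0.3, 0.3, 1, "flat", seed = 12)
  expect_equal(roc_auc(unlist(lapply(flat, `[[`, "scores")), labels), 0.5,
               tolerance = 0.015)
})

test_that("structure-derived series respond to the quality knob", {
  entries <- small_cohort(60, seed = 14)
  labels <- unlist(lapply(entries, `[[`, "disorder"))
  auc_at <- function(q) {
    af2 <- gen_af2_series(entries, quality = q, seed = 14)
    pl <- unlist(lapply(af2, function(a) plddt_to_disorder(a$plddt)$scores))
    rs <- unlist(lapply(af2, function(a) smooth_rsa(a$rsa)$scores))
    c(plddt = roc_auc(pl, labels), rsa = roc_auc(rs, labels))
  }
  a0 <- auc_at(0); a05 <- auc_at(0.5); a2 <- auc_at(2)
  expect_equal(unname(a0["plddt"]), 0.5, tolerance = 0.03)
  expect_true(all(a05 < a2))
  expect_true(all(a0["plddt"] < a05["plddt"]))
})

test_that("generated artifacts survive the IO round trip", {
  cfg <- gen_config(n_proteins = 15, length_meanlog = log(60), seed = 21)
  entries <- gen_reference(cfg)
  dir <- tempfile()
  paths <- write_reference(entries, dir, config = cfg)
  back <- read_reference(paths$disorder, paths$binding)
  expect_named(back, names(entries))
  for (id in names(entries)) {
    expect_equal(back[[id]]$sequence, entries[[id]]$sequence)
    expect_equal(back[[id]]$disorder, entries[[id]]$disorder)
    if (any(entries[[id]]$binding == 1L))
      expect_equal(back[[id]]$binding, entries[[id]]$binding)
  }
  cfg_back <- jsonlite::read_json(file.path(dir, "gen_config.json"))
  expect_equal(cfg_back$n_proteins, 15)

  prof <- gen_predictor(entries, -0.5, 0.5, 1, "m", seed = 21)
  ppath <- tempfile()
  write_prediction(prof, ppath)
  pback <- read_prediction(ppath, method = "m")
  expect_named(pback, names(prof))
  expect_equal(pback[[3]]$scores, prof[[3]]$scores, tolerance = 5e-4)
})

test_that("content error shrinks as class separation grows", {
  entries <- small_cohort(80, seed = 25)
  native <- vapply(entries, function(e) disorder_content(e$disorder), 0)
  mae_at <- function(sep) {
    prof <- gen_predictor(entries, -sep / 2, sep / 2, 1,
                          paste0("sep", sep), seed = 25)
    thr <- calibrate_threshold(prof, entries)
    pred <- vapply(names(entries), function(i)
      disorder_content(binarize(prof[[i]], thr)$binary), 0)
    content_mae(pred, native)
  }
  maes <- c(mae_at(0.5), mae_at(1.5), mae_at(3))
  expect_true(all(diff(maes) < 0))
})
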