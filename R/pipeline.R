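# ---- configuration -------------------------------------------------------------

default_config <- function() {
  list(
    experiment = "visual",          # "visual" or "auditory" synthetic study
    seed = 1,
    n_train = 96, n_test = 32,      # stimuli per split
    window = 8.82, hop = 0.735,     # sliding-window spec, seconds
    grid_length = 100,              # effective-df grid size
    permutations = 1000,
    bootstrap = 1000,
    alpha = 0.05,
    driver_measure = NULL,          # measure driving synthetic responses
    n_subjects = 3,
    subject_noise_sd = 0.4,
    response_noise_sd = 1,
    rois = list(
      R1 = list(q = 60, slope = 0.8, neg_frac = 0.10, group = "lower"),
      R2 = list(q = 48, slope = 0.6, neg_frac = 0.20, group = "lower"),
      R3 = list(q = 40, slope = 0.4, neg_frac = 0.35, group = "higher"),
      R4 = list(q = 32, slope = 0.2, neg_frac = 0.50, group = "higher")),
    image = list(clutter_range = c(0, 50), size = 256, noise_sd = 2),
    audio = list(rate_range = c(1, 8), duration = 29, sample_rate = 16000,
                 noise_sd = 0.02),
    out_dir = NULL
  )
}

#' Validate and normalize a pipeline configuration
#'
#' Fills documented defaults, rejects unknown keys, and checks the structural
#' constraints (window/hop ordering, positive permutation counts, ROI
#' definitions). Every randomized stage derives its seed from `seed`.
#'
#' @param cfg named list of overrides (possibly empty).
#' @return normalized config list.
#' @export
validate_config <- function(cfg = list()) {
  def <- default_config()
  unknown <- setdiff(names(cfg), names(def))
  if (length(unknown))
    stop("unknown config keys: ", paste(unknown, collapse = ", "))
  out <- utils::modifyList(def, cfg)
  # the ROI collection is replaced wholesale, never merged with the defaults
  if ("rois" %in% names(cfg)) out$rois <- cfg$rois
  if (!out$experiment %in% c("visual", "auditory"))
    stop("experiment must be 'visual' or 'auditory'")
  if (is.null(out$driver_measure))
    out$driver_measure <- if (out$experiment == "visual") "gradient"
                          else "flac"
  if (out$hop <= 0 || out$hop > out$window)
    stop("require 0 < hop <= window")
  if (out$permutations < 1) stop("permutations must be >= 1")
  if (out$bootstrap < 1) stop("bootstrap must be >= 1")
  if (out$n_train < 3 || out$n_test < 3) stop("need >= 3 stimuli per split")
  for (nm in names(out$rois)) {
    r <- out$rois[[nm]]
    if (is.null(r$q) || r$q < 1) stop("ROI ", nm, ": q must be >= 1")
    if (is.null(r$neg_frac) || r$neg_frac < 0 || r$neg_frac > 1)
      stop("ROI ", nm, ": neg_frac must be in [0, 1]")
  }
  out
}

config_hash <- function(cfg) {
  s <- paste(deparse(cfg[order(names(cfg))]), collapse = "")
  sprintf("%08x", sum(utf8ToInt(s) * seq_along(utf8ToInt(s))) %% 2^31)
}

provenance <- function(cfg) {
  c(sprintf("# config_hash: %s", config_hash(cfg)),
    sprintf("# seed: %d", cfg$seed),
    sprintf("# package: complexcortex %s",
            as.character(utils::packageVersion("complexcortex"))))
}

write_tsv_prov <- function(df, path, cfg) {
  con <- file(path, "w"); on.exit(close(con))
  writeLines(provenance(cfg), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# ---- vectorized encoding permutation --------------------------------------------

col_cor <- function(x, Y) {
  xc <- x - mean(x)
  Yc <- sweep(Y, 2, colMeans(Y))
  sx <- sqrt(sum(xc^2))
  sy <- sqrt(colSums(Yc^2))
  out <- drop(crossprod(Yc, xc)) / (sx * sy)
  out[!is.finite(out)] <- 0
  out
}

#' Permutation test for all encoding models of an ROI at once
#'
#' Same null scheme as [permutation_test()] — targets shuffled independently
#' within train and test, models refit and rescored — but vectorized across
#' voxels: each permutation refits every per-voxel slope and recomputes every
#' test correlation in closed form.
#'
#' @param x_train,x_test standardized targets.
#' @param Y_train,Y_test standardized trials x voxels responses.
#' @param reps permutations.
#' @param seed RNG seed.
#' @return list with per-voxel `observed` r, `p`, `chance`, and `beta`.
#' @export
encoding_permutation <- function(x_train, Y_train, x_test, Y_test,
                                 reps = 1000, seed = 1) {
  beta <- encode_roi(x_train, Y_train)
  # r(beta * x_test, y_test) = sign(beta) * cor(x_test, y_test)
  observed <- sign(beta) * col_cor(x_test, Y_test)
  observed[beta == 0] <- 0
  ge <- numeric(ncol(Y_train))
  chance_acc <- numeric(ncol(Y_train))
  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv)
  set.seed(seed)
  for (i in seq_len(reps)) {
    xp_tr <- sample(x_train)
    xp_te <- sample(x_test)
    b <- encode_roi(xp_tr, Y_train)
    r <- sign(b) * col_cor(xp_te, Y_test)
    r[b == 0] <- 0
    ge <- ge + (r >= observed)
    chance_acc <- chance_acc + r
  }
  if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv)
  list(observed = observed, p = ge / reps, chance = chance_acc / reps,
       beta = beta)
}

# ---- orchestration --------------------------------------------------------------

synth_features <- function(cfg) {
  if (cfg$experiment == "visual") {
    n <- cfg$n_train + cfg$n_test
    gen <- gen_images(n, cfg$image$clutter_range, cfg$image$size,
                      cfg$image$noise_sd, seed = cfg$seed + 101)
    feat <- visual_complexity_table(gen$images, size = cfg$image$size)
    feat$split <- rep(c("train", "test"), c(cfg$n_train, cfg$n_test))
    list(features = feat, truth = gen$clutter,
         measures = c("gradient", "png_bytes", "self_similarity"))
  } else {
    n <- cfg$n_train + cfg$n_test
    gen <- gen_audio(n, cfg$audio$rate_range, cfg$audio$duration,
                     cfg$audio$sample_rate, cfg$audio$noise_sd,
                     seed = cfg$seed + 101)
    long <- audio_complexity_table(gen$clips, window = cfg$window,
                                   hop = cfg$hop)
    # one trial per stimulus-window; wide table of per-trial measure values
    wide <- stats::reshape(long, idvar = c("stimulus_id", "window_index"),
                           timevar = "measure", direction = "wide")
    names(wide) <- sub("^value\\.", "", names(wide))
    wide$split <- rep(rep(c("train", "test"), c(cfg$n_train, cfg$n_test)),
                      each = max(long$window_index))
    names(wide)[names(wide) == "event_density"] <- "event_density"
    feat <- data.frame(stimulus_id = paste(wide$stimulus_id,
                                           wide$window_index, sep = "_"),
                       flac = wide$flac, ogg = wide$ogg,
                       event_density = wide$event_density,
                       split = wide$split, stringsAsFactors = FALSE)
    list(features = feat, truth = gen$rates,
         measures = c("flac", "ogg", "event_density"))
  }
}

#' Run the full synthetic encoding/decoding pipeline
#'
#' Generates synthetic stimuli, computes the three complexity measures,
#' plants voxel responses driven by the standardized driver measure,
#' synthesizes subjects as transformed copies, hyperaligns them, fits
#' decoding and encoding models per ROI and measure, runs permutation tests
#' and bootstrap SEMs, and produces the measure-correlation, overlap and
#' sensitivity summaries. Deterministic given `cfg$seed`.
#'
#' @param cfg configuration list (see [validate_config()]).
#' @return list with `features`, `measure_correlations`, `decoding` score
#'   table, `encoding` per-voxel table, `overlap` fractions per ROI group,
#'   and `sensitivity` table; written under `cfg$out_dir` when set.
#' @export
run_pipeline <- function(cfg = list()) {
  cfg <- validate_config(cfg)
  sf <- synth_features(cfg)
  feat <- sf$features
  measures <- sf$measures
  is_tr <- feat$split == "train"

  cors <- stats::cor(as.matrix(feat[, measures]))
  driver <- feat[[cfg$driver_measure]]
  x_tr_raw <- driver[is_tr]; x_te_raw <- driver[!is_tr]
  mx <- mean(x_tr_raw); sx <- pop_sd(x_tr_raw)
  x_tr <- (x_tr_raw - mx) / sx; x_te <- (x_te_raw - mx) / sx

  slopes <- plant_slopes(cfg$rois, seed = cfg$seed + 202)
  dec_rows <- list(); enc_rows <- list(); sens_rows <- list()
  masks_by_group <- list()
  for (ri in seq_along(cfg$rois)) {
    roi <- names(cfg$rois)[ri]
    rcfg <- cfg$rois[[ri]]
    common_tr <- gen_responses(x_tr, slopes[[roi]], cfg$response_noise_sd,
                               seed = cfg$seed + 300 + ri, roi = roi,
                               split = "train")
    common_te <- gen_responses(x_te, slopes[[roi]], cfg$response_noise_sd,
                               seed = cfg$seed + 400 + ri, roi = roi,
                               split = "test")
    subs_tr <- gen_subjects(common_tr, cfg$n_subjects,
                            noise_sd = cfg$subject_noise_sd,
                            seed = cfg$seed + 500 + ri)
    # apply the same planted transforms to the test split, plus fresh noise
    subs_te <- vector("list", cfg$n_subjects)
    set.seed(cfg$seed + 600 + ri)
    for (s in seq_len(cfg$n_subjects)) {
      X <- apply_transform(common_te$data, subs_tr$transforms[[s]])
      X <- X + matrix(stats::rnorm(length(X), 0, cfg$subject_noise_sd),
                      nrow(X))
      subs_te[[s]] <- response_matrix(X, subject = paste0("S", s), roi = roi,
                                      split = "test")
    }
    cs <- hyperalign(subs_tr$subjects, iterations = 2)
    sh <- project(subs_tr$subjects, subs_te, cs)

    for (m in measures) {
      xm_tr <- feat[[m]][is_tr]; xm_te <- feat[[m]][!is_tr]
      std <- standardize_pair(list(x = xm_tr, Y = sh$train$data),
                              list(x = xm_te, Y = sh$test$data))
      # decoding
      dm <- fit_decoding(std$train$Y, std$train$x,
                         grid_length = cfg$grid_length)
      ev <- evaluate(dm, std$test$x, std$test$Y)
      sv <- svd(std$train$Y)
      dec_null <- permutation_test(
        function(tr, te) {
          md <- fit_decoding(tr$Y, tr$x, grid_length = cfg$grid_length,
                             sv = sv)
          evaluate(md, te$x, te$Y)$r
        },
        train = list(x = std$train$x, Y = std$train$Y),
        test = list(x = std$test$x, Y = std$test$Y),
        reps = cfg$permutations, seed = cfg$seed + 700 + ri)
      sem <- bootstrap_sem(std$test$x, ev$predictions, reps = cfg$bootstrap,
                           seed = cfg$seed + 800 + ri)
      dec_rows[[length(dec_rows) + 1L]] <- data.frame(
        roi = roi, group = rcfg$group, measure = m, model = "decoding",
        r = ev$r, p = dec_null$p, chance = dec_null$chance, sem = sem,
        lambda = dm$lambda, edf = dm$edf, stringsAsFactors = FALSE)
      # encoding (vectorized across voxels)
      ep <- encoding_permutation(std$train$x, std$train$Y, std$test$x,
                                 std$test$Y, reps = cfg$permutations,
                                 seed = cfg$seed + 900 + ri)
      enc_rows[[length(enc_rows) + 1L]] <- data.frame(
        roi = roi, group = rcfg$group, measure = m,
        voxel = seq_along(ep$beta), beta = ep$beta, r = ep$observed,
        p = ep$p, stringsAsFactors = FALSE)
      sens <- sensitivity_summary(ep$beta, ep$observed,
                                  significance_mask(ep$p)$p05)
      if (!is.null(sens))
        sens_rows[[length(sens_rows) + 1L]] <- data.frame(
          roi = roi, group = rcfg$group, measure = m,
          mean_abs_beta = sens$mean_abs_beta,
          pct_positive = sens$pct_positive,
          mean_abs_beta_over_r = sens$mean_abs_beta_over_r,
          n_sig = sens$n_sig, stringsAsFactors = FALSE)
      masks_by_group[[rcfg$group]][[m]] <-
        c(masks_by_group[[rcfg$group]][[m]],
          significance_mask(ep$p)$p05)
    }
  }
  overlap <- lapply(masks_by_group, overlap_fractions)
  out <- list(config = cfg, features = feat, measure_correlations = cors,
              decoding = do.call(rbind, dec_rows),
              encoding = do.call(rbind, enc_rows),
              sensitivity = do.call(rbind, sens_rows),
              overlap = overlap)
  if (!is.null(cfg$out_dir)) {
    dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
    write_tsv_prov(out$decoding, file.path(cfg$out_dir, "decoding_scores.tsv"),
                   cfg)
    write_tsv_prov(out$encoding, file.path(cfg$out_dir, "encoding_voxels.tsv"),
                   cfg)
    write_tsv_prov(out$sensitivity,
                   file.path(cfg$out_dir, "sensitivity.tsv"), cfg)
    write_tsv_prov(feat, file.path(cfg$out_dir, "features.tsv"), cfg)
    jsonlite::write_json(
      list(measure_correlations = as.data.frame(cors),
           overlap = lapply(overlap, as.list)),
      file.path(cfg$out_dir, "summaries.json"), auto_unbox = TRUE,
      digits = NA)
  }
  out
}
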