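# Run configuration and command entry points. A single YAML-serializable
# config drives the reproducible commands (fixtures / train / sample /
# evaluate / selftest); every run writes a JSON manifest capturing the config
# snapshot, seed, package version and input hashes, so identical manifests
# imply identical outputs for the deterministic commands.

default_run_config <- function() {
  list(
    seed = 1L,
    vocabulary = list(symbols = c("H", "C", "N", "O", "F")),
    fixtures = list(templates = c("methane", "water", "formaldehyde", "ethane"),
                    count = 50L, jitter_sd = 0.02),
    diffusion = list(beta_min = 0.1, beta_max = 20, T_end = 1),
    network = list(L_H = 4L, L_R = 4L, L_A = 4L, K = 3L, heads = 4L,
                   hidden = 128L, use_cosine = TRUE, use_equivariant = TRUE,
                   fused_xp_network = FALSE),
    train = list(steps = 300L, batch_size = 32L, lr = 1e-3, t_min = 1e-5,
                 gamma = "sigma_sq", ema_decay = 0.999, clip_norm = 1.0,
                 lr_schedule = "cosine", sample_weights = "uniform"),
    sampler = list(n_steps = 1000L, M = 1L, snr = 0.16, t_min = 1e-3,
                   denoise_final = TRUE),
    evaluate = list(bonds = "geometry"),
    n_samples = 100L,
    paths = list(out_dir = ".")
  )
}

#' Run configuration
#'
#' Builds the full nested configuration for the command entry points,
#' validating against the default template: unknown keys are rejected.
#'
#' @param ... named overrides of top-level sections (partial lists are merged
#'   into the defaults).
#' @param file optional YAML file to load (then `...` overrides on top).
#' @return A list of class `"run_config"`.
#' @export
run_config <- function(..., file = NULL) {
  cfg <- default_run_config()
  if (!is.null(file)) cfg <- merge_config(cfg, yaml::read_yaml(file), "config")
  cfg <- merge_config(cfg, list(...), "argument")
  class(cfg) <- "run_config"
  cfg
}

merge_config <- function(base, upd, where) {
  if (length(upd) == 0L) return(base)
  unknown <- setdiff(names(upd), names(base))
  if (length(unknown) > 0L) {
    stop("unknown ", where, " key(s): ", paste(unknown, collapse = ", "))
  }
  for (nm in names(upd)) {
    base[[nm]] <- if (is.list(base[[nm]]) && is.list(upd[[nm]])) {
      merge_config(base[[nm]], upd[[nm]], paste0(where, "$", nm))
    } else {
      v <- upd[[nm]]
      if (is.integer(base[[nm]]) && is.numeric(v)) v <- as.integer(v)
      v
    }
  }
  base
}

#' Write a run configuration to YAML
#' @param cfg a [run_config()].
#' @param file output path.
#' @export
write_run_config <- function(cfg, file) {
  yaml::write_yaml(unclass(cfg), file)
  invisible(file)
}

# Apply flat "section.key=value" override strings (CLI syntax).
apply_overrides <- function(cfg, overrides) {
  for (ov in overrides) {
    kv <- strsplit(ov, "=", fixed = TRUE)[[1L]]
    if (length(kv) != 2L) stop("override must be section.key=value: ", ov)
    path <- strsplit(kv[1L], ".", fixed = TRUE)[[1L]]
    val <- utils::type.convert(kv[2L], as.is = TRUE)
    node <- cfg
    for (p in path) {
      if (is.null(node[[p]])) stop("unknown config key: ", kv[1L])
      node <- node[[p]]
    }
    cfg[[path]] <- if (length(node) > 1L) {
      utils::type.convert(strsplit(kv[2L], ",", fixed = TRUE)[[1L]], as.is = TRUE)
    } else val
    if (is.integer(node)) cfg[[path]] <- as.integer(cfg[[path]])
  }
  cfg
}

cfg_objects <- function(cfg) {
  vocab <- atom_vocabulary(cfg$vocabulary$symbols)
  d <- cfg$diffusion
  sch <- function() noise_schedule(d$beta_min, d$beta_max, d$T_end)
  list(vocab = vocab,
       spec = diffusion_spec(sch(), sch(), sch()),
       network = do.call(network_config, cfg$network),
       train = do.call(train_config, c(cfg$train, list(seed = cfg$seed))),
       sampler = do.call(sampler_config, cfg$sampler))
}

write_manifest <- function(cfg, command, out_dir, inputs = character(0),
                           extra = list()) {
  hashes <- if (length(inputs) > 0L) as.list(tools::md5sum(inputs)) else list()
  man <- c(list(command = command, seed = cfg$seed,
                package_version = as.character(utils::packageVersion("scoremol")),
                config = unclass(cfg), input_hashes = hashes,
                timestamp = format(Sys.time(), tz = "UTC")), extra)
  path <- file.path(out_dir, paste0(command, "_manifest.json"))
  jsonlite::write_json(man, path, auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(path)
}

#' Run a reproducible command
#'
#' Entry points behind the command-line script: `fixtures` (generate and dump
#' a synthetic dataset), `train` (fit the model on an SDF or on fixtures),
#' `sample` (generate molecules from a checkpoint), `evaluate` (stability
#' report + geometry histograms for an SDF), `selftest` (equivariance and
#' solver oracle suites). Every command writes a JSON manifest next to its
#' outputs; all randomness flows from `cfg$seed`.
#'
#' @param name one of `"fixtures"`, `"train"`, `"sample"`, `"evaluate"`,
#'   `"selftest"`.
#' @param cfg a [run_config()].
#' @param input input path where applicable (SDF for train/evaluate,
#'   checkpoint for sample).
#' @param verbose print progress.
#' @return invisibly, a list of produced artifact paths (and command-specific
#'   results).
#' @export
run_command <- function(name = c("fixtures", "train", "sample", "evaluate",
                                 "selftest"),
                        cfg = run_config(), input = NULL, verbose = FALSE) {
  name <- match.arg(name)
  ob <- cfg_objects(cfg)
  out_dir <- cfg$paths$out_dir
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  switch(name,
    fixtures = {
      fspec <- fixture_spec(cfg$fixtures$templates, cfg$fixtures$count,
                            cfg$fixtures$jitter_sd, cfg$seed)
      mols <- make_fixtures(fspec, ob$vocab)
      out <- file.path(out_dir, "fixtures.sdf")
      write_molecules(mols, out)
      man <- write_manifest(cfg, "fixtures", out_dir, out)
      invisible(list(sdf = out, manifest = man, n = length(mols)))
    },
    train = {
      mols <- if (is.null(input)) {
        make_fixtures(fixture_spec(cfg$fixtures$templates, cfg$fixtures$count,
                                   cfg$fixtures$jitter_sd, cfg$seed), ob$vocab)
      } else read_molecules(input, vocab = ob$vocab)
      metrics <- file.path(out_dir, "metrics.csv")
      fit <- scoremol(mols, ob$vocab, ob$spec, ob$network, ob$train,
                      metrics_file = metrics, verbose = verbose)
      ckpt <- file.path(out_dir, "checkpoint.rds")
      saveRDS(fit, ckpt)
      man <- write_manifest(cfg, "train", out_dir,
                            c(if (!is.null(input)) input, ckpt),
                            list(final_loss = fit$history$total[nrow(fit$history)]))
      invisible(list(checkpoint = ckpt, metrics = metrics, manifest = man,
                     fit = fit))
    },
    sample = {
      if (is.null(input)) stop("`input` must be a train checkpoint (.rds)")
      fit <- readRDS(input)
      res <- simulate(fit, nsim = cfg$n_samples, seed = cfg$seed,
                      sampler = ob$sampler)
      out <- file.path(out_dir, "samples.sdf")
      write_molecules(res$molecules, out)
      man <- write_manifest(cfg, "sample", out_dir, c(input, out),
                            list(com_drift = res$com_drift))
      invisible(list(sdf = out, manifest = man, result = res))
    },
    evaluate = {
      if (is.null(input)) stop("`input` must be an SDF of molecules")
      mols <- read_molecules(input, vocab = ob$vocab)
      rep <- stability_report(mols, bonds = cfg$evaluate$bonds, vocab = ob$vocab)
      out <- file.path(out_dir, "stability_report.json")
      jsonlite::write_json(unclass(rep), out, auto_unbox = TRUE, pretty = TRUE,
                           digits = NA)
      hg <- geometry_histograms(mols, bonds = cfg$evaluate$bonds, vocab = ob$vocab)
      hcsv <- file.path(out_dir, "histograms.csv")
      hrow <- function(kind, nm, df) {
        data.frame(kind = rep(kind, nrow(df)), key = rep(nm, nrow(df)),
                   lower = df$lower, upper = df$upper, count = df$count)
      }
      rows <- do.call(rbind, c(
        lapply(names(hg$lengths), function(nm) hrow("length", nm, hg$lengths[[nm]])),
        lapply(names(hg$angles), function(nm) hrow("angle", nm, hg$angles[[nm]]))))
      if (is.null(rows)) {
        rows <- data.frame(kind = character(0), key = character(0),
                           lower = numeric(0), upper = numeric(0),
                           count = integer(0))
      }
      utils::write.csv(rows, hcsv, row.names = FALSE)
      man <- write_manifest(cfg, "evaluate", out_dir, c(input, out))
      if (verbose) print(rep)
      invisible(list(report = rep, json = out, histograms = hcsv,
                     manifest = man))
    },
    selftest = {
      res <- selftest_suite(cfg, ob, verbose = verbose)
      out <- file.path(out_dir, "selftest.json")
      jsonlite::write_json(res, out, auto_unbox = TRUE, pretty = TRUE,
                           digits = NA)
      man <- write_manifest(cfg, "selftest", out_dir, out)
      if (!isTRUE(res$pass)) stop("selftest failed; see ", out)
      invisible(list(results = res, json = out, manifest = man))
    })
}

# Equivariance battery + solver oracle, runnable from a fresh checkout.
selftest_suite <- function(cfg = run_config(), ob = cfg_objects(cfg),
                           n_trials = 25L, verbose = FALSE) {
  set.seed(cfg$seed)
  nets <- score_networks(ob$vocab, ob$network, seed = cfg$seed)
  spec <- ob$spec
  errs <- equivariance_battery(nets, spec, n_trials = n_trials)
  sch <- spec$schedule_X
  score_fn <- function(u, t) {
    co <- vp_coefficients(t, sch)
    -u / (co$alpha^2 * 0.25 + co$sigma^2)
  }
  u <- pc_sample_component(score_fn, 5000L,
                           sampler_config(n_steps = 200L, M = 1L), sch)
  solver <- list(mean = mean(u), var = stats::var(u))
  pass <- max(errs$score_X, errs$score_P, errs$score_A) < 1e-5 &&
    abs(solver$mean) < 0.05 && abs(solver$var - 0.25) < 0.05
  if (verbose) {
    message(sprintf("equivariance max rel. err: X %.2e P %.2e A %.2e",
                    errs$score_X, errs$score_P, errs$score_A))
    message(sprintf("solver moments: mean %.4f var %.4f", solver$mean,
                    solver$var))
  }
  list(equivariance = errs, solver = solver, pass = pass)
}

#' E(3)/permutation equivariance battery
#'
#' Over random (rotation or reflection, permutation) pairs applied to random
#' noised states, measures the maximum relative error of: score_X invariance,
#' score_P equivariance, score_A invariance, and permutation equivariance of
#' all three.
#'
#' @param nets a `"score_networks"`.
#' @param spec a [diffusion_spec()].
#' @param n_trials number of random trials.
#' @param N atom count of the random states.
#' @return list of maximum relative errors per network.
#' @export
equivariance_battery <- function(nets, spec = diffusion_spec(),
                                 n_trials = 100L, N = 5L) {
  k <- nets$k
  rel <- function(a, b) max(abs(a - b)) / (max(abs(b)) + 1e-12)
  ex <- ep <- ea <- 0
  for (i in seq_len(n_trials)) {
    t <- stats::runif(1, 0.05, spec$T_end)
    st <- sample_prior(N, k, spec)
    st$t <- t
    R <- qr.Q(qr(matrix(stats::rnorm(9), 3)))
    if (i %% 2L == 0L) R[, 1L] <- -R[, 1L]  # include reflections
    pm <- sample.int(N)
    sx <- score_x_net(st, nets, spec)
    sp <- score_p_net(st, nets, spec)
    sa <- score_a_net(st, nets, spec)
    st_r <- noised_state(st$X, st$P %*% R, st$A, t)
    ex <- max(ex, rel(score_x_net(st_r, nets, spec), sx))
    ep <- max(ep, rel(score_p_net(st_r, nets, spec), sp %*% R))
    ea <- max(ea, rel(score_a_net(st_r, nets, spec), sa))
    st_p <- noised_state(st$X[pm, , drop = FALSE], st$P[pm, , drop = FALSE],
                         st$A[pm, pm], t)
    ex <- max(ex, rel(score_x_net(st_p, nets, spec), sx[pm, , drop = FALSE]))
    ep <- max(ep, rel(score_p_net(st_p, nets, spec), sp[pm, , drop = FALSE]))
    ea <- max(ea, rel(score_a_net(st_p, nets, spec), sa[pm, pm]))
  }
  list(score_X = ex, score_P = ep, score_A = ea)
}
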