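#' Featurization options
#'
#' @param backend_dim trainable embedding width (default 128).
#' @param backend_seed seed for the backend lookup table.
#' @param max_len truncation length L for the token stream (default 512).
#' @param pseaac_cfg a [pseaac_config()].
#' @param dpc_keep retained dipeptide features (default 229).
#' @param blocks fused-vector blocks, a subset of
#'   `c("embedding", "pseaac", "dpc")` in that fixed order.
#' @return A `feature_options` list.
#' @export
feature_options <- function(backend_dim = 128L, backend_seed = 0L,
                            max_len = 512L, pseaac_cfg = pseaac_config(),
                            dpc_keep = 229L,
                            blocks = c("embedding", "pseaac", "dpc")) {
  blocks <- intersect(c("embedding", "pseaac", "dpc"), blocks)
  structure(list(backend_dim = as.integer(backend_dim),
                 backend_seed = as.integer(backend_seed),
                 max_len = as.integer(max_len), pseaac_cfg = pseaac_cfg,
                 dpc_keep = as.integer(dpc_keep), blocks = blocks),
            class = "feature_options")
}

#' Featurize a dataset with train-only transform fitting
#'
#' Computes the token stream (integer-encoded residues, truncated at
#' `max_len`) and the fused per-sequence descriptor: the mask-weighted mean
#' of the frozen backend embedding (128), the PseAAC vector (25) and the
#' variance-selected DPC vector (229), concatenated in that order and
#' z-score normalized. The DPC selector and the normalizer are fitted
#' exclusively on the rows named in `train_ids` and applied frozen
#' elsewhere; the ids they saw are recorded in `fitted_on_ids`.
#'
#' @param ds a labeled `protein_dataset`.
#' @param train_ids ids of the training split (transform-fitting rows).
#' @param opts a [feature_options()].
#' @return A `feature_set`: `ids`, `labels` (0/1), `tokens` (list),
#'   `fused` (normalized matrix or `NULL` when no blocks), `slices`,
#'   `selector`, `normalizer`, `fitted_on_ids`, `opts`.
#' @export
featurize_dataset <- function(ds, train_ids, opts = feature_options()) {
  stopifnot(inherits(ds, "protein_dataset"))
  if (!all(train_ids %in% ds$id)) stop("train_ids must be dataset ids")
  n <- nrow(ds)
  tokens <- lapply(ds$residues, tokenize, max_len = opts$max_len)
  train_rows <- ds$id %in% train_ids
  blocks <- list(); slices <- list(); selector <- NULL
  if ("embedding" %in% opts$blocks) {
    backend <- embedding_backend("trainable", token_dim = opts$backend_dim,
                                 max_len = opts$max_len,
                                 seed = opts$backend_seed)
    emb <- t(vapply(tokens, function(tk) colMeans(
      backend$table[tk, , drop = FALSE]), numeric(opts$backend_dim)))
    blocks$embedding <- emb
  }
  if ("pseaac" %in% opts$blocks) {
    blocks$pseaac <- t(vapply(ds$residues, pseaac, cfg = opts$pseaac_cfg,
                              FUN.VALUE = numeric(20L + opts$pseaac_cfg$lambda_),
                              USE.NAMES = FALSE))
  }
  if ("dpc" %in% opts$blocks) {
    d400 <- t(vapply(ds$residues, dpc, FUN.VALUE = numeric(400L),
                     USE.NAMES = FALSE))
    selector <- fit_dpc_selector(d400[train_rows, , drop = FALSE],
                                 keep = opts$dpc_keep)
    blocks$dpc <- apply_dpc_selector(selector, d400)
  }
  fused <- NULL; normalizer <- NULL
  if (length(blocks)) {
    fused_raw <- do.call(cbind, blocks)
    ends <- unname(cumsum(vapply(blocks, ncol, integer(1))))
    starts <- c(1L, utils::head(ends, -1) + 1L)
    slices <- Map(function(s, e) c(start = s, end = e), starts, ends)
    names(slices) <- names(blocks)
    normalizer <- fit_normalizer(fused_raw[train_rows, , drop = FALSE])
    fused <- apply_normalizer(normalizer, fused_raw)
  }
  structure(list(ids = ds$id, labels = as.integer(ds$label == "CML"),
                 tokens = tokens, fused = fused, slices = slices,
                 selector = selector, normalizer = normalizer,
                 fitted_on_ids = ds$id[train_rows], opts = opts),
            class = "feature_set")
}

# trainer-format subset of a feature_set
feature_subset <- function(fs, ids) {
  idx <- match(ids, fs$ids)
  if (anyNA(idx)) stop("unknown ids in subset")
  list(tokens = fs$tokens[idx],
       fused = if (is.null(fs$fused)) NULL else
         fs$fused[idx, , drop = FALSE],
       labels = fs$labels[idx], ids = fs$ids[idx])
}

#' Ablation variant definitions
#'
#' Maps each variant name to its architecture and fused-descriptor
#' configuration: `cnn_only` drops the BiLSTM, `bilstm_only` drops both
#' convolution branches, `single_cnn_bilstm` keeps only the k=3 branch,
#' `dual_no_handcrafted` disables late fusion, `dual_pseaac_only` /
#' `dual_dpc_only` fuse a single handcrafted block, and `full` is the
#' complete model. Baseline variants (no handcrafted descriptors) run
#' without late fusion.
#'
#' @param name one of `"cnn_only"`, `"bilstm_only"`, `"single_cnn_bilstm"`,
#'   `"dual_no_handcrafted"`, `"dual_pseaac_only"`, `"dual_dpc_only"`,
#'   `"full"`.
#' @return List with `name`, `spec_args` (toggles for [model_spec()]) and
#'   `blocks` (fused-vector blocks).
#' @export
ablation_variant <- function(name) {
  variants <- list(
    cnn_only = list(spec_args = list(use_bilstm = FALSE,
                                     use_late_fusion = FALSE),
                    blocks = character(0)),
    bilstm_only = list(spec_args = list(use_branch_a = FALSE,
                                        use_branch_b = FALSE,
                                        use_late_fusion = FALSE),
                       blocks = character(0)),
    single_cnn_bilstm = list(spec_args = list(use_branch_b = FALSE,
                                              use_late_fusion = FALSE),
                             blocks = character(0)),
    dual_no_handcrafted = list(spec_args = list(use_late_fusion = FALSE),
                               blocks = character(0)),
    dual_pseaac_only = list(spec_args = list(), blocks = "pseaac"),
    dual_dpc_only = list(spec_args = list(), blocks = "dpc"),
    full = list(spec_args = list(), blocks = c("embedding", "pseaac", "dpc")))
  if (!name %in% names(variants)) stop("unknown variant name: ", name)
  c(list(name = name), variants[[name]])
}

#' Experiment configuration
#'
#' One config object drives the whole pipeline: data source (generator or
#' FASTA), optional redundancy filtering, stratified split, featurization,
#' architecture variant, and training. All randomness derives from the
#' single root `seed`. Redundancy filtering defaults to off: exact
#' all-pairs global alignment is quadratic in corpus size and the
#' synthetic corpus is duplicate-free by construction; enable it for real
#' corpora via `dedupe_threshold`.
#'
#' @param generator a [generator_config()] (or `NULL` to read FASTA).
#' @param fasta,manifest input files when `generator` is `NULL`.
#' @param dedupe_threshold identity threshold for [filter_redundant()], or
#'   `NULL` to skip the stage.
#' @param fractions split proportions (train, validation, test).
#' @param variant ablation variant name (default `"full"`).
#' @param feature_opts a [feature_options()]; its `blocks` are overridden
#'   by the variant.
#' @param train training parameters as a [train_config()].
#' @param model_args extra overrides for [model_spec()] (e.g. smaller
#'   `filters` for quick experiments).
#' @param bootstrap bootstrap resamples for the report CIs.
#' @param seed root seed.
#' @return An `experiment_config`.
#' @export
experiment_config <- function(generator = generator_config(), fasta = NULL,
                              manifest = NULL, dedupe_threshold = NULL,
                              fractions = c(0.70, 0.15, 0.15),
                              variant = "full",
                              feature_opts = feature_options(),
                              train = train_config(),
                              model_args = list(), bootstrap = 1000L,
                              seed = 0L) {
  structure(list(generator = generator, fasta = fasta, manifest = manifest,
                 dedupe_threshold = dedupe_threshold, fractions = fractions,
                 variant = variant, feature_opts = feature_opts,
                 train = train, model_args = model_args,
                 bootstrap = as.integer(bootstrap), seed = as.integer(seed)),
            class = "experiment_config")
}

#' Run an end-to-end experiment
#'
#' Executes (dedupe ->) split -> featurize (transforms fitted on the
#' training split only) -> train -> evaluate-on-test, with every source of
#' randomness seeded from `config$seed`. Returns the evaluation report and
#' a manifest sufficient to reproduce the run bit-compatibly on the same
#' backend (timings are recorded separately and excluded from any
#' reproducibility comparison).
#'
#' @param config an [experiment_config()].
#' @param keep_model return the trained model (default `TRUE`).
#' @return List with `manifest`, `report` (an `eval_report`), `history`,
#'   `model` (optionally), `features`, `splits` (ids per split), and
#'   `scores` on the test split.
#' @export
run_experiment <- function(config = experiment_config(), keep_model = TRUE) {
  stopifnot(inherits(config, "experiment_config"))
  t0 <- proc.time()[["elapsed"]]
  timings <- c()
  tic <- function() proc.time()[["elapsed"]]
  variant <- ablation_variant(config$variant)

  # stage: data
  t_stage <- tic()
  if (!is.null(config$generator)) {
    gen <- generate_dataset(config$generator)
    ds <- gen$dataset
    truth <- gen$motif_positions
  } else {
    if (is.null(config$fasta)) stop("either a generator or a FASTA is required")
    ds <- read_fasta(config$fasta, config$manifest)
    truth <- NULL
  }
  content_hash <- dataset_hash(ds)
  timings["data"] <- tic() - t_stage

  # stage: dedupe (optional; see experiment_config)
  dedupe_report <- NULL
  if (!is.null(config$dedupe_threshold)) {
    t_stage <- tic()
    fr <- filter_redundant(ds, config$dedupe_threshold)
    ds <- fr$dataset
    dedupe_report <- fr$report
    timings["dedupe"] <- tic() - t_stage
  }

  # stage: split
  t_stage <- tic()
  splits <- stratified_split(ds, split_spec(fractions = config$fractions,
                                            seed = config$seed + 1L))
  timings["split"] <- tic() - t_stage

  # stage: featurize (fit on train only)
  t_stage <- tic()
  fopts <- config$feature_opts
  fopts$blocks <- variant$blocks
  fopts$backend_seed <- config$seed + 2L
  fs <- featurize_dataset(ds, train_ids = splits$train$id, opts = fopts)
  parts <- lapply(splits, function(sp) feature_subset(fs, sp$id))
  timings["featurize"] <- tic() - t_stage

  # stage: model + training
  t_stage <- tic()
  fusion_dim <- if (is.null(fs$fused) || !length(variant$blocks)) 0L else {
    sum(vapply(fs$slices[variant$blocks], function(sl)
      sl["end"] - sl["start"] + 1L, integer(1)))
  }
  spec_args <- c(variant$spec_args, config$model_args)
  spec_args$use_late_fusion <- fusion_dim > 0L
  spec_args$fusion_dim <- fusion_dim
  spec <- do.call(model_spec, spec_args)
  model <- build_model(spec, seed = config$seed + 3L)
  tcfg <- config$train
  tcfg$seed <- config$seed + 4L
  trained <- train_model(model, trim_blocks(parts$train, variant$blocks, fs),
                         trim_blocks(parts$validation, variant$blocks, fs),
                         tcfg)
  timings["train"] <- tic() - t_stage

  # stage: evaluate on test
  t_stage <- tic()
  test_part <- trim_blocks(parts$test, variant$blocks, fs)
  probs <- predict_proba(trained$model, test_part)
  scores <- probs[, "CML"]
  report <- eval_report(test_part$labels, scores,
                        bootstrap = config$bootstrap,
                        seed = config$seed + 5L)
  timings["evaluate"] <- tic() - t_stage

  manifest <- list(
    package_version = as.character(utils::packageVersion("seqfuse")),
    seed = config$seed,
    stage_seeds = c(split = config$seed + 1L, backend = config$seed + 2L,
                    model = config$seed + 3L, train = config$seed + 4L,
                    bootstrap = config$seed + 5L),
    variant = variant$name,
    content_hash = content_hash,
    n_sequences = nrow(ds),
    split_counts = lapply(splits, function(sp) as.list(class_counts(sp))),
    split_ids = lapply(splits, function(sp) sp$id),
    fusion_dim = fusion_dim,
    parameter_count = count_parameters(trained$model),
    fitted_on_ids = fs$fitted_on_ids,
    best_epoch = attr(trained$history, "best_epoch"),
    stopped_epoch = attr(trained$history, "stopped_epoch"),
    dedupe = if (is.null(dedupe_report)) NULL else
      list(threshold = dedupe_report$threshold,
           removed = length(dedupe_report$removed)),
    environment = list(r_version = as.character(getRversion())))
  out <- list(manifest = manifest, report = report,
              history = trained$history, features = fs,
              splits = lapply(splits, function(sp) sp$id),
              scores = scores, test_labels = test_part$labels,
              motif_truth = truth, timings = timings,
              total_elapsed = tic() - t0)
  if (keep_model) out$model <- trained$model
  out
}

# restrict a trainer-format part to the variant's fused blocks
trim_blocks <- function(part, blocks, fs) {
  if (!length(blocks) || is.null(part$fused)) {
    part$fused <- NULL
    return(part)
  }
  cols <- unlist(lapply(fs$slices[blocks], function(sl)
    sl["start"]:sl["end"]), use.names = FALSE)
  part$fused <- part$fused[, cols, drop = FALSE]
  part
}

# content hash of a dataset: md5 of its canonical FASTA serialization
dataset_hash <- function(ds) {
  tf <- tempfile(fileext = ".fasta")
  on.exit(unlink(tf))
  write_fasta(ds, tf)
  unname(tools::md5sum(tf))
}

#' Run the ablation grid
#'
#' Trains each variant `n_repeats` times on seeds
#' `config$seed + 10 * run_index`, summarizes each metric as mean with a
#' percentile-bootstrap 95% CI over the repeats, and reports two-tailed
#' paired t-tests of every variant against `"full"` (pairing by seed).
#'
#' @param config an [experiment_config()] (its `variant` is ignored).
#' @param variants character vector of [ablation_variant()] names.
#' @param n_repeats seeded repetitions per variant (default 10).
#' @param metric_ci_B bootstrap resamples for the CI over repeats.
#' @return List with `table` (one row per variant: mean and CI for
#'   accuracy and ROC-AUC, p-values vs full when present), `runs`
#'   (per-run metrics), `tests`.
#' @export
run_ablation <- function(config, variants, n_repeats = 10L,
                         metric_ci_B = 1000L) {
  if (length(variants) < 2L) stop("need at least 2 variants")
  for (v in variants) ablation_variant(v)  # validate names early
  runs <- list()
  for (v in variants) {
    acc <- auc <- numeric(n_repeats)
    for (r in seq_len(n_repeats)) {
      cfg <- config
      cfg$variant <- v
      cfg$seed <- config$seed + 10L * r
      cfg$bootstrap <- 0L
      res <- run_experiment(cfg, keep_model = FALSE)
      acc[r] <- res$report$metrics$accuracy
      auc[r] <- res$report$roc_auc
    }
    runs[[v]] <- data.frame(run = seq_len(n_repeats), accuracy = acc,
                            roc_auc = auc)
  }
  # percentile bootstrap over the per-run metric values
  boot_mean_ci <- function(x) {
    v <- with_seed(config$seed, vapply(seq_len(metric_ci_B), function(b) {
      mean(sample(x, replace = TRUE))
    }, numeric(1)))
    q <- unname(stats::quantile(v, c(0.025, 0.975), type = 7))
    c(lower = q[1], upper = q[2])
  }
  tab <- do.call(rbind, lapply(names(runs), function(v) {
    r <- runs[[v]]
    ca <- boot_mean_ci(r$accuracy)
    cu <- boot_mean_ci(r$roc_auc)
    data.frame(variant = v, accuracy_mean = mean(r$accuracy),
               accuracy_lower = ca["lower"], accuracy_upper = ca["upper"],
               roc_auc_mean = mean(r$roc_auc),
               roc_auc_lower = cu["lower"], roc_auc_upper = cu["upper"],
               row.names = NULL, stringsAsFactors = FALSE)
  }))
  tests <- list()
  tab$p_accuracy_vs_full <- NA_real_
  if ("full" %in% names(runs)) {
    for (v in setdiff(names(runs), "full")) {
      tests[[v]] <- list(
        accuracy = paired_ttest(runs$full$accuracy, runs[[v]]$accuracy),
        roc_auc = paired_ttest(runs$full$roc_auc, runs[[v]]$roc_auc))
      tab$p_accuracy_vs_full[tab$variant == v] <-
        tests[[v]]$accuracy$p_value
    }
    tab$p_accuracy_vs_full[tab$variant == "full"] <- NA_real_
  }
  list(table = tab, runs = runs, tests = tests)
}
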