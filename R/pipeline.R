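# Command-level pipeline: simulate / fuse / train / evaluate, each driven by
# a config list (usually parsed from YAML). Every command writes a resolved
# copy of its configuration next to its outputs so any run can be repeated
# exactly. A thin Rscript wrapper around these functions is installed at
# inst/cli/stackfuse.

resolve_outdir <- function(out_dir) {
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  normalizePath(out_dir)
}

write_resolved_config <- function(cfg, out_dir, name) {
  path <- file.path(out_dir, paste0(name, "_config.yaml"))
  yaml::write_yaml(cfg, path)
  invisible(path)
}

#' Simulate a synthetic dataset onto disk
#'
#' Wraps [make_dataset()]: renders the stacks, writes the decimated input
#' stacks, full stacks, wavelet targets and all-in-focus references as TIFF
#' files, and records a JSON manifest. Presets: `"tbf"` (14 planes at
#' 0.5 um, 6.5 um slab, thick-film-like) and `"pbs"` (7 planes at 0.5 um,
#' 3 um slab, thin-smear-like; default).
#'
#' @param cfg list with optional entries `preset`, `n_stacks`,
#'   `decimation_factor`, `seed`, `out_dir`, plus any [stack_config()]
#'   override.
#' @return manifest list, invisibly; files under `cfg$out_dir`.
#' @export
cmd_simulate <- function(cfg = list()) {
  preset <- cfg$preset %||% "pbs"
  base <- switch(preset,
    tbf = stack_config(n_planes = 14L, sample_thickness = 6.5),
    pbs = stack_config(n_planes = 7L, sample_thickness = 3.0),
    stop("unknown preset '", preset, "' (use 'tbf' or 'pbs')"))
  for (nm in intersect(names(cfg), names(base))) base[[nm]] <- cfg[[nm]]
  n_stacks <- cfg$n_stacks %||% 10L
  k <- cfg$decimation_factor %||% 2L
  seed <- cfg$seed %||% 1L
  out_dir <- resolve_outdir(cfg$out_dir %||% "simulated")
  ds <- make_dataset(n_stacks, base, decimation_factor = k, seed = seed)
  entries <- vector("list", n_stacks)
  for (i in seq_len(n_stacks)) {
    id <- sprintf("stack_%03d", i)
    in_path <- file.path(out_dir, paste0(id, "_input.tiff"))
    full_path <- file.path(out_dir, paste0(id, "_full.tiff"))
    tgt_path <- file.path(out_dir, paste0(id, "_target.tiff"))
    ref_path <- file.path(out_dir, paste0(id, "_reference.tiff"))
    write_stack(ds[[i]]$input, in_path)
    write_stack(ds[[i]]$full, full_path)
    tiff::writeTIFF(ds[[i]]$target$image, tgt_path, bits.per.sample = 16L)
    tiff::writeTIFF(ds[[i]]$reference, ref_path, bits.per.sample = 16L)
    entries[[i]] <- list(id = id, input = basename(in_path),
                         full = basename(full_path),
                         target = basename(tgt_path),
                         reference = basename(ref_path))
  }
  manifest <- list(preset = preset, n_stacks = n_stacks,
                   decimation_factor = k, seed = seed,
                   stack_config = base, stacks = entries)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  write_resolved_config(c(cfg, list(preset = preset, n_stacks = n_stacks,
                                    decimation_factor = k, seed = seed)),
                        out_dir, "simulate")
  invisible(manifest)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Fuse stacks from disk
#'
#' Reads multi-page TIFF stacks and writes one fused EDoF image (16-bit
#' TIFF) plus a JSON provenance sidecar per stack. `method = "wavelet"` runs
#' the multi-scale-decomposition baseline; `method = "cami"` runs the
#' network and requires a checkpoint.
#'
#' @param cfg list with `inputs` (character vector of stack TIFF paths),
#'   `method`, `out_dir`, optional `checkpoint`, `axial_step`, and wavelet
#'   config overrides (`wavelet_name`, `levels`, ...).
#' @return character vector of output paths, invisibly.
#' @export
cmd_fuse <- function(cfg) {
  method <- cfg$method %||% "wavelet"
  if (!method %in% c("wavelet", "cami"))
    stop("unknown fusion method '", method, "' (use 'wavelet' or 'cami')")
  inputs <- cfg$inputs
  if (is.null(inputs) || length(inputs) == 0L) stop("no input stacks given")
  out_dir <- resolve_outdir(cfg$out_dir %||% "fused")
  params <- NULL
  if (method == "cami") {
    if (is.null(cfg$checkpoint)) stop("method 'cami' requires a checkpoint")
    params <- load_checkpoint(cfg$checkpoint)$params
  }
  wcfg <- wavelet_fusion_config(
    wavelet_name = cfg$wavelet_name %||% "sym4",
    levels = cfg$levels %||% 4L,
    consistency_radius = cfg$consistency_radius %||% 1L)
  outs <- character(length(inputs))
  for (i in seq_along(inputs)) {
    stack <- read_stack(inputs[i], axial_step = cfg$axial_step)
    fused <- if (method == "wavelet") fuse_stack_wavelet(stack, wcfg)
             else cami_fuse(stack, params)
    out <- file.path(out_dir, paste0(sub("\\.[Tt][Ii][Ff][Ff]?$", "",
                                         basename(inputs[i])),
                                     "_", method, ".tiff"))
    tiff::writeTIFF(fused$image, out, bits.per.sample = 16L)
    jsonlite::write_json(list(method = fused$method,
                              source = inputs[i],
                              source_planes = fused$source_planes,
                              source_step = fused$source_step),
                         sidecar_path(out), auto_unbox = TRUE, digits = NA)
    outs[i] <- out
  }
  write_resolved_config(cfg, out_dir, "fuse")
  invisible(outs)
}

#' Train a fusion model from a simulated dataset directory
#'
#' Reads the manifest written by [cmd_simulate()], loads input stacks and
#' targets, trains the network and writes a checkpoint plus the per-step
#' loss history CSV.
#'
#' @param cfg list with `data_dir` (a [cmd_simulate()] output directory),
#'   `n_steps`, `out_dir`, optional `checkpoint` to resume from, and any
#'   [fusion_net_config()] field override (`NL`, `Ed`, `patch_size`, ...).
#' @return list with `checkpoint` path and `history`, invisibly.
#' @export
cmd_train <- function(cfg) {
  if (is.null(cfg$data_dir)) stop("'data_dir' is required")
  manifest <- jsonlite::read_json(file.path(cfg$data_dir, "manifest.json"),
                                  simplifyVector = TRUE)
  out_dir <- resolve_outdir(cfg$out_dir %||% "trained")
  ncfg <- fusion_net_config(
    NL = cfg$NL %||% 2L, Ed = cfg$Ed %||% 16L,
    n_res_blocks = cfg$n_res_blocks %||% 5L,
    patch_size = cfg$patch_size %||% 64L,
    learning_rate = cfg$learning_rate %||% 1e-4,
    batch_size = cfg$batch_size %||% 2L,
    seed = cfg$seed %||% 1L)
  dataset <- lapply(seq_len(nrow(manifest$stacks)), function(i) {
    input <- read_stack(file.path(cfg$data_dir, manifest$stacks$input[i]))
    tgt <- tiff::readTIFF(file.path(cfg$data_dir, manifest$stacks$target[i]))
    list(input = input, target = tgt)
  })
  warm <- if (!is.null(cfg$checkpoint)) load_checkpoint(cfg$checkpoint) else NULL
  fit <- train_fusion_net(dataset, ncfg, n_steps = cfg$n_steps %||% 500L,
                          params = warm$params,
                          verbose = isTRUE(cfg$verbose))
  if (!is.null(warm) && !is.null(warm$history))
    fit$history <- rbind(warm$history,
                         transform(fit$history,
                                   step = step + max(warm$history$step)))
  ckpt <- file.path(out_dir, "checkpoint.rds")
  save_checkpoint(fit$params, ckpt, history = fit$history)
  utils::write.csv(fit$history, file.path(out_dir, "loss_history.csv"),
                   row.names = FALSE)
  write_resolved_config(cfg, out_dir, "train")
  invisible(list(checkpoint = ckpt, history = fit$history))
}

#' Evaluate fused images against references
#'
#' Compares two equal-length sets of single-image TIFFs pairwise with SSIM,
#' Pearson correlation and HaarPSI, writing one CSV row per pair.
#'
#' @param cfg list with `references` and `tests` (character vectors of TIFF
#'   paths, matched by position) and `out_dir`.
#' @return the `metric_report` data frame, invisibly; CSV under `out_dir`.
#' @export
cmd_evaluate <- function(cfg) {
  refs <- cfg$references; tests <- cfg$tests
  if (length(refs) != length(tests))
    stop("reference and test sets must have equal length")
  if (length(refs) == 0L) stop("empty evaluation sets")
  out_dir <- resolve_outdir(cfg$out_dir %||% "evaluation")
  load_img <- function(p) {
    img <- tiff::readTIFF(p)
    if (length(dim(img)) == 2L) img <- array(rep(img, 3L), c(dim(img), 3L))
    img[, , 1:3, drop = FALSE]
  }
  report <- evaluate_batch(lapply(refs, load_img), lapply(tests, load_img))
  report$reference_id <- basename(refs)
  report$test_id <- basename(tests)
  utils::write.csv(report, file.path(out_dir, "metrics.csv"), row.names = FALSE)
  write_resolved_config(cfg, out_dir, "evaluate")
  invisible(report)
}
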