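# Reproducible pipelines: a YAML stage list driving simulate -> convert ->
# smooth -> glm (plus tf / contrast), with a file manifest carrying input
# hashes and the package version.

#' Run a configured analysis pipeline
#'
#' Stages execute in order inside `workdir`; every file an executed stage
#' produces is recorded in a manifest (with its MD5 hash and the package
#' version) written as `manifest.csv`. Any failure aborts with an error
#' naming the stage; stages already completed keep their outputs.
#'
#' Supported stages and their parameter blocks:
#' \describe{
#'   \item{simulate}{`seed`, plus any [simulation_spec] field; writes a
#'     dataset container under `out`.}
#'   \item{convert}{`dataset` (container dir), `out`, `n_pixels`,
#'     `bad_channel_mode`, `average` (logical: average epochs first).}
#'   \item{smooth}{`fwhm` (vector, physical units), `images` (dir or
#'     manifest of stage `convert`), `out`.}
#'   \item{glm}{`design` (one-sample / two-sample / paired), `groups` or
#'     `n`, `contrast` (weights), `type` (t / F), `alpha`, `images`
#'     (smoothed dir), optional `window` (list of `c(lo, hi)` voxel
#'     ranges); writes `results.csv`.}
#' }
#'
#' @param config path to a YAML config, or an equivalent list with a
#'   `stages` element.
#' @param workdir working directory for all relative paths.
#' @param seed optional integer overriding every stage seed.
#' @return list with `status` (0 on success), `manifest` data.frame, and
#'   per-stage `results`.
#' @export
run_pipeline <- function(config, workdir = ".", seed = NULL) {
  cfg <- if (is.character(config)) yaml::read_yaml(config) else config
  if (is.null(cfg$stages)) stop("config has no stages")
  known <- c("simulate", "convert", "smooth", "glm")
  for (st in cfg$stages)
    if (!st$stage %in% known)
      stop("unknown stage '", st$stage, "'")
  manifest <- NULL
  results <- list()
  state <- new.env(parent = emptyenv())
  for (st in cfg$stages) {
    t0 <- proc.time()[3]
    out <- tryCatch(
      .run_stage(st, workdir, seed, state),
      error = function(e) stop("stage '", st$stage, "' failed: ",
                               conditionMessage(e), call. = FALSE))
    if (length(out$files) > 0)
      manifest <- rbind(manifest, data.frame(
        stage = st$stage, file = out$files,
        md5 = unname(tools::md5sum(out$files)),
        version = as.character(utils::packageVersion("topostat"))))
    results[[st$stage]] <- out$result
    message(sprintf("[topostat] stage %-8s %5.1fs", st$stage,
                    proc.time()[3] - t0))
  }
  if (!is.null(manifest)) {
    mf <- file.path(workdir, "manifest.csv")
    utils::write.csv(manifest, mf, row.names = FALSE)
    manifest <- rbind(manifest)
  }
  list(status = 0L, manifest = manifest, results = results)
}

.run_stage <- function(st, workdir, seed, state) {
  p <- st
  path <- function(x) file.path(workdir, x)
  switch(st$stage,
    simulate = {
      args <- p[setdiff(names(p), c("stage", "out"))]
      if (!is.null(seed)) args$seed <- seed
      if (!is.null(args$epoch_ms)) args$epoch_ms <- unlist(args$epoch_ms)
      if (!is.null(args$conditions)) args$conditions <- unlist(args$conditions)
      spec <- do.call(simulation_spec, args)
      ds <- gen_dataset(spec)
      write_dataset(ds, path(p$out))
      state$dataset <- path(p$out)
      list(files = list.files(path(p$out), full.names = TRUE),
           result = spec)
    },
    convert = {
      dsdir <- if (!is.null(p$dataset)) path(p$dataset) else state$dataset
      ds <- read_dataset(dsdir)
      if (isTRUE(p$average) && inherits(ds, "epoched_dataset"))
        ds <- average_epochs(ds)
      grid <- NULL
      man <- dataset_to_volumes(
        ds, path(p$out), name = basename(dsdir), grid = grid,
        bad_channel_mode = if (is.null(p$bad_channel_mode)) "interpolate"
        else p$bad_channel_mode)
      state$converted <- man
      list(files = man$file, result = man)
    },
    smooth = {
      files <- if (!is.null(p$images))
        list.files(path(p$images), pattern = "\\.nii$", recursive = TRUE,
                   full.names = TRUE)
      else state$converted$file
      fwhm <- unlist(p$fwhm)
      outdir <- path(p$out)
      outs <- character(0)
      for (f in files) {
        img <- read_stat_image(f)
        sm <- gaussian_smooth_image(img, rep_len(fwhm,
                                                 length(dim(img$data))))
        of <- file.path(outdir, basename(dirname(f)), basename(f))
        dir.create(dirname(of), recursive = TRUE, showWarnings = FALSE)
        write_stat_image(sm, of)
        outs <- c(outs, of)
      }
      state$smoothed <- outs
      list(files = outs, result = outs)
    },
    glm = {
      files <- if (!is.null(p$images))
        list.files(path(p$images), pattern = "\\.nii$", recursive = TRUE,
                   full.names = TRUE)
      else state$smoothed
      design <- if (!is.null(p$groups))
        build_design(p$design, groups = unlist(p$groups))
      else build_design(p$design, n = p$n)
      model <- fit_glm(as.character(files), design)
      con <- compute_contrast(model, unlist(p$contrast),
                              type = if (is.null(p$type)) NULL else p$type)
      sm <- estimate_smoothness(model)
      window <- NULL
      if (!is.null(p$window)) {
        window <- array(FALSE, model$dims)
        rg <- lapply(p$window, function(w) seq(w[[1]], w[[2]]))
        window[rg[[1]], rg[[2]], rg[[3]]] <- TRUE
      }
      tab <- topological_report(con, sm,
                                alpha = if (is.null(p$alpha)) 0.05
                                else p$alpha,
                                window = window)
      rf <- path(if (is.null(p$out)) "results.csv" else p$out)
      dir.create(dirname(rf), recursive = TRUE, showWarnings = FALSE)
      utils::write.csv(as.data.frame(tab), rf, row.names = FALSE)
      list(files = rf, result = tab)
    })
}
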