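#' Configure an end-to-end pipeline run
#'
#' A run processes one case — either a phantom generated on the fly or an
#' image read from disk — through preprocessing, each requested
#' segmentation backend, arm removal, VAT/SAT delineation, surface
#' quantification and (when reference masks are available) evaluation.
#'
#' @param phantom Optional [phantom_spec()]; generated at run time.
#' @param image_path Optional path to an input slice (TIFF/PNG);
#'   exactly one of `phantom`/`image_path` must be given.
#' @param ref_sat_path,ref_vat_path Optional reference compartment mask
#'   paths (evaluation is skipped without them; phantoms carry their own
#'   ground truth).
#' @param abdominal_mask_path Optional manual abdominal mask; when absent
#'   the mask is built automatically ([build_abdominal_mask()]).
#' @param methods Subset of `c("otsu", "kmeans", "fcm")`.
#' @param preprocess A [preprocess_config()].
#' @param geometry A [pixel_geometry()] for the case's FOV and grid.
#' @param seed Integer seed governing every stochastic stage of the case.
#' @param out_dir Output directory; created if missing. `NULL` disables
#'   file output.
#' @param case_id Label used in output file names and tables.
#' @return An object of class `run_config`.
#' @export
run_config <- function(phantom = NULL, image_path = NULL,
                       ref_sat_path = NULL, ref_vat_path = NULL,
                       abdominal_mask_path = NULL,
                       methods = c("otsu", "kmeans", "fcm"),
                       preprocess = preprocess_config(),
                       geometry = NULL, seed = 1L, out_dir = NULL,
                       case_id = "case") {
  methods <- match.arg(methods, c("otsu", "kmeans", "fcm"), several.ok = TRUE)
  if (is.null(phantom) == is.null(image_path)) {
    stop("supply exactly one of `phantom` or `image_path`", call. = FALSE)
  }
  if (!is.null(phantom)) stopifnot(inherits(phantom, "phantom_spec"))
  if (!is.null(geometry)) stopifnot(inherits(geometry, "pixel_geometry"))
  structure(list(phantom = phantom, image_path = image_path,
                 ref_sat_path = ref_sat_path, ref_vat_path = ref_vat_path,
                 abdominal_mask_path = abdominal_mask_path,
                 methods = methods, preprocess = preprocess,
                 geometry = geometry, seed = as.integer(seed),
                 out_dir = out_dir, case_id = case_id),
            class = "run_config")
}

#' Run one case end-to-end
#'
#' Executes the automated branch of the workflow for every configured
#' segmentation backend and, when an output directory is set, writes the
#' preprocessed image, per-method adipose/SAT/VAT masks, a `surfaces.csv`
#' and `evaluation.csv`, and a `manifest.json` capturing the
#' configuration, seed, package version and per-method results, so a run
#' is reproducible byte for byte from its manifest.
#'
#' @param cfg A [run_config()].
#' @return A list with `case_id`, `surfaces` (data.frame), `evaluation`
#'   (data.frame or `NULL`), per-method `compartments`, and `manifest`.
#' @export
run_case <- function(cfg) {
  stopifnot(inherits(cfg, "run_config"))
  if (!is.null(cfg$phantom)) {
    ph <- generate_slice_phantom(cfg$phantom)
    img <- ph$image
    ref <- ph$ground_truth
    abdominal <- ph$abdominal_mask
  } else {
    img <- read_image(cfg$image_path)
    ref <- if (!is.null(cfg$ref_sat_path) && !is.null(cfg$ref_vat_path)) {
      compartment_masks(read_mask(cfg$ref_sat_path), read_mask(cfg$ref_vat_path))
    }
    abdominal <- NULL
  }
  if (!is.null(cfg$abdominal_mask_path)) {
    abdominal <- read_mask(cfg$abdominal_mask_path)
  }
  if (is.null(abdominal)) abdominal <- build_abdominal_mask(img)

  geom <- cfg$geometry
  if (is.null(geom)) {
    # 1 mm pixels when no FOV is supplied; surfaces then count cm² of px
    geom <- pixel_geometry(nrow(img), ncol(img), nrow(img), ncol(img))
  }
  pre <- enhance(img, cfg$preprocess)

  out_dir <- cfg$out_dir
  if (!is.null(out_dir) && !dir.exists(out_dir)) {
    dir.create(out_dir, recursive = TRUE)
  }
  save_file <- function(writer, obj, name) {
    if (!is.null(out_dir)) writer(obj, file.path(out_dir, name))
  }
  save_file(write_image, quantize8(pre), paste0(cfg$case_id, "_preprocessed.tif"))

  surfaces <- list(); evals <- list(); compartments <- list()
  for (method in cfg$methods) {
    scfg <- segmentation_config(method, seed = cfg$seed)
    seg <- segment_slice(pre, scfg)
    adipose <- apply_abdominal_mask(seg$mask, abdominal)
    comp <- delineate_vat_sat(adipose)
    compartments[[method]] <- comp
    rep_area <- distribution_indices(surface(comp$sat, geom),
                                     surface(comp$vat, geom))
    surfaces[[method]] <- data.frame(case = cfg$case_id, method = method,
                                     sat_cm2 = rep_area$sat_cm2,
                                     vat_cm2 = rep_area$vat_cm2,
                                     tat_cm2 = rep_area$tat_cm2,
                                     vat_tat_pct = rep_area$vat_tat_pct,
                                     vat_sat_ratio = rep_area$vat_sat_ratio,
                                     stringsAsFactors = FALSE)
    if (!is.null(ref)) {
      ev <- eval_report(comp, ref, method)
      ev <- cbind(case = cfg$case_id, ev, stringsAsFactors = FALSE)
      evals[[method]] <- ev
    }
    save_file(write_mask, adipose, paste0(cfg$case_id, "_", method, "_adipose.png"))
    save_file(write_mask, comp$sat, paste0(cfg$case_id, "_", method, "_sat.png"))
    save_file(write_mask, comp$vat, paste0(cfg$case_id, "_", method, "_vat.png"))
  }
  surfaces <- do.call(rbind, surfaces)
  evaluation <- if (length(evals)) do.call(rbind, c(evals, make.row.names = FALSE))

  manifest <- list(
    case_id = cfg$case_id,
    seed = cfg$seed,
    package_version = as.character(utils::packageVersion("slicefat")),
    methods = cfg$methods,
    preprocess = unclass(cfg$preprocess),
    geometry = if (!is.null(cfg$geometry)) unclass(cfg$geometry),
    phantom = if (!is.null(cfg$phantom)) unclass(cfg$phantom),
    image_path = cfg$image_path,
    surfaces = surfaces
  )
  if (!is.null(out_dir)) {
    write.csv(surfaces, file.path(out_dir, paste0(cfg$case_id, "_surfaces.csv")),
              row.names = FALSE)
    if (!is.null(evaluation)) {
      write.csv(evaluation, file.path(out_dir, paste0(cfg$case_id, "_evaluation.csv")),
                row.names = FALSE)
    }
    jsonlite::write_json(manifest, file.path(out_dir, paste0(cfg$case_id, "_manifest.json")),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE,
                         dataframe = "rows")
  }
  list(case_id = cfg$case_id, surfaces = surfaces, evaluation = evaluation,
       compartments = compartments, manifest = manifest)
}

# Quantize to 8-bit levels so written TIFFs round-trip losslessly.
quantize8 <- function(img) round(pmin(pmax(img, 0), 1) * 255) / 255

#' Compare segmentation methods across cases
#'
#' Summarizes pooled evaluation rows (from [run_case()] or
#' [eval_report()]) per method and compartment as mean ± SD of Dice and
#' Hausdorff, and tests each pair of methods with the paired Wilcoxon
#' signed-rank test on the per-case Dice values. All-zero difference
#' vectors (identical methods) are reported as p = 1.
#'
#' @param evaluation Data.frame with columns `case`, `method`,
#'   `compartment`, `dice`, `hausdorff_px`; every method must cover the
#'   same case set.
#' @return A list with `summary` (method x compartment table) and
#'   `pairwise` (Wilcoxon p-values per compartment and method pair).
#' @export
compare_methods <- function(evaluation) {
  needed <- c("case", "method", "compartment", "dice", "hausdorff_px")
  stopifnot(all(needed %in% names(evaluation)))
  methods <- unique(evaluation$method)
  if (length(methods) < 2) stop("need at least two methods", call. = FALSE)
  case_sets <- split(evaluation$case, evaluation$method)
  base_set <- sort(unique(case_sets[[1]]))
  for (m in methods) {
    if (!identical(sort(unique(case_sets[[m]])), base_set)) {
      stop("method '", m, "' does not cover the same case set", call. = FALSE)
    }
  }
  summary_tab <- aggregate(cbind(dice, hausdorff_px) ~ method + compartment,
                           data = evaluation,
                           FUN = function(x) c(mean = mean(x), sd = sd(x)),
                           na.action = stats::na.pass)
  pairs <- utils::combn(methods, 2, simplify = FALSE)
  rows <- list()
  for (comp in unique(evaluation$compartment)) {
    sub <- evaluation[evaluation$compartment == comp, ]
    for (pr in pairs) {
      a <- sub[sub$method == pr[1], ]
      b <- sub[sub$method == pr[2], ]
      a <- a[order(a$case), ]; b <- b[order(b$case), ]
      d <- a$dice - b$dice
      p <- if (all(d == 0)) 1 else
        suppressWarnings(wilcox.test(a$dice, b$dice, paired = TRUE)$p.value)
      rows[[length(rows) + 1L]] <- data.frame(
        compartment = comp, method_a = pr[1], method_b = pr[2],
        mean_dice_diff = mean(d), p_value = p, stringsAsFactors = FALSE)
    }
  }
  list(summary = summary_tab, pairwise = do.call(rbind, rows))
}
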