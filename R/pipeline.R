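#' Pipeline run configuration
#'
#' All documented defaults are the method's published operating point:
#' 1.0 A lattice spacing, 5 A first-layer cutoff, 3 A second-layer
#' cutoff, 6 A trim, 1.0 A clash tolerance, 0.5 A contact padding, merge
#' threshold of 5 bits.
#'
#' @param spacing Lattice spacing (A).
#' @param flr_cutoff First-layer residue cutoff (A).
#' @param slr_cutoff Second-layer residue cutoff (A).
#' @param trim_cutoff Lattice trim distance (A).
#' @param ctd Clash tolerance distance (A).
#' @param cpd Contact padding distance (A).
#' @param merge_threshold Strict Hamming merge threshold (bits); 0
#'   disables merging.
#' @param k Cluster count or `"auto"`.
#' @param dims MDS dimensions.
#' @param cavity_min_dirs,cavity_range Buriedness test knobs, see
#'   [generate_pocket_points()].
#' @param outlier_rmsd Mobile structures whose backbone superposition
#'   rmsd exceeds this (A) are dropped with a warning.
#' @param flr_keys Manual first-layer residue keys (apo-template mode);
#'   `NULL` selects them from the ligand ensemble.
#' @param seed Integer seed (recorded; the pipeline itself is
#'   deterministic).
#' @return A named list of class `run_config`.
#' @export
run_config <- function(spacing = 1.0, flr_cutoff = 5.0, slr_cutoff = 3.0,
                       trim_cutoff = 6.0, ctd = 1.0, cpd = 0.5,
                       merge_threshold = 5L, k = "auto", dims = 3,
                       cavity_min_dirs = 4, cavity_range = 14.0,
                       outlier_rmsd = 1.0, flr_keys = NULL, seed = 1L) {
  structure(
    list(
      spacing = spacing, flr_cutoff = flr_cutoff, slr_cutoff = slr_cutoff,
      trim_cutoff = trim_cutoff, ctd = ctd, cpd = cpd,
      merge_threshold = merge_threshold, k = k, dims = dims,
      cavity_min_dirs = cavity_min_dirs, cavity_range = cavity_range,
      outlier_rmsd = outlier_rmsd, flr_keys = flr_keys, seed = seed
    ),
    class = "run_config"
  )
}

stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    stop("pipeline stage '", name, "' failed: ", conditionMessage(e), call. = FALSE)
  })
}

#' Run the full pocket-shape pipeline
#'
#' Executes superposition, first-layer selection, alanine enlargement,
#' lattice generation, second-layer selection, rotamer prefiltering,
#' exhaustive conformer enumeration, point classification, bit-string
#' encoding, deduplication, merging, clustering with medoid selection,
#' ligand incompatibility profiling and key-residue ranking. All stage
#' outputs are written as plain-text tables plus a machine-readable
#' summary; a rerun with the same inputs and config is byte-identical.
#'
#' @param template Template `pocket_structure` or PDB path.
#' @param holo List of ligand-bound `pocket_structure` objects or PDB
#'   paths (may be empty with manual `config$flr_keys`).
#' @param library Rotamer library tibble or TSV path.
#' @param out_dir Output directory (created if needed); `NULL` skips
#'   writing.
#' @param config A [run_config()].
#' @return Invisible list with all intermediate objects and `$summary`.
#' @export
run_pipeline <- function(template, holo = list(), library, out_dir = NULL,
                         config = run_config()) {
  if (is.character(template)) template <- read_structure(template)
  holo <- lapply(holo, function(h) if (is.character(h)) read_structure(h) else h)
  if (is.character(library)) library <- load_rotamer_library(library)
  library <- validate_rotamer_library(library)

  sup <- stage("superpose", {
    rmsds <- numeric(0)
    kept <- list()
    for (h in holo) {
      sp <- superpose_backbone(h, template)
      if (sp$rmsd > config$outlier_rmsd) {
        warning(
          "dropping ", h$source, ": backbone rmsd ", round(sp$rmsd, 3),
          " A exceeds the outlier threshold"
        )
        next
      }
      rmsds <- c(rmsds, sp$rmsd)
      kept[[length(kept) + 1]] <- apply_superposition(h, sp)
    }
    list(structures = kept, rmsds = rmsds)
  })

  ensemble <- stage("ligand_ensemble", {
    if (length(sup$structures) > 0) {
      build_ligand_ensemble(sup$structures)
    } else {
      build_ligand_ensemble(list(template))
    }
  })

  flr <- stage("flr", {
    if (!is.null(config$flr_keys)) {
      residue_table(template) |> dplyr::filter(.data$res_key %in% config$flr_keys)
    } else {
      select_flr(template, ensemble, cutoff = config$flr_cutoff)
    }
  })

  ala <- stage("ala_substitute", ala_substitute(template, flr$res_key))

  lattice <- stage("lattice", generate_pocket_points(
    ala, ensemble, flr$res_key,
    spacing = config$spacing, trim_cutoff = config$trim_cutoff,
    cavity_min_dirs = config$cavity_min_dirs, cavity_range = config$cavity_range
  ))

  cparams <- contact_params(cpd = config$cpd)
  slr <- stage("slr", select_slr(
    template, lattice, flr$res_key,
    cutoff = config$slr_cutoff, params = cparams
  ))

  kparams <- clash_params(ctd = config$ctd)
  placements <- stage(
    "rotamer_prefilter",
    prefilter_rotamers(template, library, slr$res_key, params = kparams)
  )
  graph <- stage("interaction_graph", build_interaction_graph(placements))
  conformers <- stage("enumerate", enumerate_conformers(graph))

  csets <- stage("contact_sets", rotamer_contact_sets(placements, lattice, cparams))
  per_conf <- stage("conformer_contacts", conformer_contact_sets(conformers, csets))
  points <- stage("classify_points", classify_points(lattice, per_conf))
  per_res_cond <- lapply(csets, function(per_rot) {
    sort(intersect(unique(unlist(per_rot)), points$conditional))
  })
  points$ccr_keys <- stage("ccr", identify_ccrs(slr$res_key, per_res_cond))

  bits <- stage("encode", encode_conformers(conformers, csets, points))
  strings <- stage("deduplicate", deduplicate(bits, point_ids = points$conditional))
  merged <- stage("merge", merge_similar(strings, threshold_bits = config$merge_threshold))

  d <- stage("dissimilarity", dissimilarity_matrix(merged))
  model <- stage("cluster", fit_shape_clusters(d, k = config$k, dims = config$dims))

  lig_volumes <- stage("ligand_volumes", {
    if (nrow(ensemble) == 0) {
      list()
    } else {
      split(ensemble, ensemble$ligand_id) |>
        lapply(function(la) encode_ligand_volume(la, lattice, cparams, ligand_id = la$ligand_id[1]))
    }
  })
  profile <- if (length(lig_volumes) > 0) {
    stage("incompatibility", incompatibility_profile(lig_volumes, merged, points))
  } else {
    NULL
  }

  key_res <- stage("key_residues", key_residue_association(
    merged, conformers, model$embedding, model$labels,
    residues = intersect(colnames(conformers), points$ccr_keys)
  ))

  n_conf <- nrow(conformers)
  summary <- list(
    n_structures = length(sup$structures) + 1,
    mean_ca_rmsd = if (length(sup$rmsds) > 0) mean(sup$rmsds) else NA_real_,
    n_flr = nrow(flr),
    n_slr = nrow(slr),
    n_ccr = length(points$ccr_keys),
    n_points = nrow(lattice$points),
    n_always_free = length(points$always_free),
    n_always_contact = length(points$always_contact),
    n_conditional = length(points$conditional),
    n_conformers = n_conf,
    n_unique_strings = nrow(strings$bits),
    n_merged_strings = nrow(merged$bits),
    fold_reduction = n_conf / nrow(strings$bits),
    k = model$k,
    avg_silhouette = model$avg_silhouette,
    top_residue = if (nrow(key_res) > 0) key_res$res_key[1] else NA_character_
  )

  result <- list(
    summary = summary, config = config, template = template,
    superposed = sup$structures, ensemble = ensemble, flr = flr,
    ala = ala, lattice = lattice, slr = slr, placements = placements,
    graph = graph, conformers = conformers, points = points,
    strings = strings, merged = merged, diss = d, model = model,
    ligand_volumes = lig_volumes, profile = profile, key_residues = key_res
  )
  if (!is.null(out_dir)) write_pipeline_outputs(result, out_dir)
  invisible(result)
}

# Serialise the pipeline outputs as deterministic plain-text files.
write_pipeline_outputs <- function(result, out_dir) {
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  p <- function(f) file.path(out_dir, f)
  readr::write_tsv(result$flr, p("flr.tsv"))
  readr::write_tsv(result$slr, p("slr.tsv"))
  readr::write_tsv(points_table(result$points), p("points.tsv"))
  readr::write_tsv(conformer_table(result$conformers, result$placements), p("conformers.tsv"))
  readr::write_tsv(tibble::as_tibble(result$merged), p("strings.tsv"))
  d_out <- tibble::as_tibble(result$diss, rownames = "string_id")
  readr::write_tsv(d_out, p("dissimilarity.tsv"))
  readr::write_tsv(tidy(result$model), p("clusters.tsv"))
  if (!is.null(result$profile)) {
    readr::write_tsv(
      tibble::as_tibble(result$profile, rownames = "string_id"),
      p("incompatibility.tsv")
    )
  }
  readr::write_tsv(result$key_residues, p("key_residues.tsv"))
  cfg <- unclass(result$config)
  cfg$flr_keys <- if (is.null(cfg$flr_keys)) NA else cfg$flr_keys
  jsonlite::write_json(cfg, p("config.json"), auto_unbox = TRUE, pretty = TRUE, digits = NA)
  jsonlite::write_json(result$summary, p("summary.json"), auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(out_dir)
}
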