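# Pipeline driver: the full two-system x two-state comparison from a single
# declarative configuration, with provenance manifest and deterministic
# CSV/JSON outputs.

default_params <- function() {
  list(hbond_distance = 3.5, hbond_angle = 30,
       contact_cutoff = 4.5, contact_persistence = 0.75,
       node_selection = "C5'", n_pcs = 3, k_paths = 1000,
       source = NULL, sink = NULL)
}

#' Assemble a pipeline run configuration
#'
#' `systems` is a named list; each system provides either file inputs
#' (`topology`, `trajectory`, `annotation`, `pairs`) or a `synthetic`
#' [synthetic_spec()] (annotation and pairs then default to the spec's).
#' Analysis parameters default to the conventional values: 3.5 A / 30 deg
#' hydrogen bonds, 4.5 A / 75% contact filter, C5' nodes, k = 1000 paths.
#' `comparisons` lists pairs of system names whose betweenness profiles are
#' compared by SIP.
#'
#' @param systems named list of system input descriptions.
#' @param params named list overriding entries of the default parameter set.
#' @param comparisons list of 2-element character vectors of system names.
#' @param seed integer seed for any synthetic generation.
#' @return a `run_config` list with all defaults resolved.
#' @export
run_config <- function(systems, params = list(), comparisons = list(), seed = 1) {
  p <- utils::modifyList(default_params(), params)
  stopifnot(is.list(systems), length(systems) >= 1, !is.null(names(systems)))
  for (nm in names(systems)) {
    sys <- systems[[nm]]
    if (is.null(sys$synthetic)) {
      for (f in c("topology", "trajectory")) {
        if (is.null(sys[[f]])) stopf("system '%s' needs %s or synthetic", nm, f)
        if (!file.exists(sys[[f]])) stopf("system '%s': missing file %s", nm, sys[[f]])
      }
    }
  }
  for (cmp in comparisons)
    if (!all(cmp %in% names(systems)))
      stopf("comparison references unknown system(s): %s", paste(cmp, collapse = ","))
  structure(list(systems = systems, params = p, comparisons = comparisons,
                 seed = as.integer(seed)),
            class = "run_config")
}

#' Load a pipeline configuration from YAML
#'
#' @param path YAML file with fields systems, params, comparisons, seed.
#' @return a `run_config`.
#' @export
load_config <- function(path) {
  y <- yaml::read_yaml(path)
  systems <- y$systems
  for (nm in names(systems)) {
    if (!is.null(systems[[nm]]$synthetic))
      systems[[nm]]$synthetic <- do.call(synthetic_spec, systems[[nm]]$synthetic)
  }
  run_config(systems, params = y$params %||% list(),
             comparisons = y$comparisons %||% list(),
             seed = y$seed %||% 1)
}

load_system_inputs <- function(sys, name, seed_offset = 0) {
  if (!is.null(sys$synthetic)) {
    spec <- sys$synthetic
    ref <- make_reference(spec)
    trj <- make_trajectory(ref, spec)
    list(reference = ref, trajectory = trj,
         annotation = default_annotation(spec),
         pairs = default_pairs(spec), spec = spec)
  } else {
    ref <- read_pdb(sys$topology)
    trj <- read_multimodel_trajectory(sys$trajectory, ref)
    ann <- if (!is.null(sys$annotation)) load_annotation(sys$annotation, ref)
           else annotation(list(whole = sort(unique(ref$atom$resno))), ref)
    prs <- if (!is.null(sys$pairs)) utils::read.csv(sys$pairs) else NULL
    list(reference = ref, trajectory = trj, annotation = ann, pairs = prs,
         spec = NULL)
  }
}

run_stage <- function(outdir, stage, expr) {
  t0 <- proc.time()[["elapsed"]]
  res <- tryCatch(expr, error = function(e) {
    writeLines(sprintf("stage %s: %s", stage, conditionMessage(e)),
               file.path(outdir, "FAILED"))
    stopf("pipeline stage '%s' failed: %s", stage, conditionMessage(e))
  })
  message(sprintf("[pipeline] %-22s %6.2f s", stage,
                  proc.time()[["elapsed"]] - t0))
  res
}

num <- function(x) as.numeric(x)

#' Run the full analysis pipeline
#'
#' Per system: substructure RMSD table, heavy-atom RMSF profile, hydrogen-bond
#' occupancy and pair-distance tables, PCA (variance fractions, PC1-PC2
#' projections, per-PC RMSF, PC1-PC2 cluster labels), DCCM, persistent
#' contact mask, `-log|C|` network with betweenness/eigenvector centrality,
#' and (when source/sink are set) the Yen path ensemble with node degeneracy
#' and nodes-per-path summary. Requested comparisons report the SIP between
#' betweenness profiles. A JSON manifest records the package version, the
#' effective parameters, the seed and input hashes. Outputs are plain CSV/JSON
#' and bit-identical across reruns of the same configuration.
#'
#' @param config a `run_config` (or path to a YAML config).
#' @param outdir output directory, one subdirectory per system.
#' @return invisibly, the manifest list.
#' @export
run_pipeline <- function(config, outdir) {
  if (is.character(config)) config <- load_config(config)
  stopifnot(inherits(config, "run_config"))
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  p <- config$params
  manifest <- list(package = "ribonet",
                   version = as.character(utils::packageVersion("ribonet")),
                   seed = config$seed, params = p,
                   systems = list(), comparisons = list())
  profiles <- list()

  for (nm in names(config$systems)) {
    sysdir <- file.path(outdir, nm)
    dir.create(sysdir, showWarnings = FALSE, recursive = TRUE)
    inp <- run_stage(sysdir, paste0(nm, ":load"),
                     load_system_inputs(config$systems[[nm]], nm))
    trj <- inp$trajectory; ann <- inp$annotation

    run_stage(sysdir, paste0(nm, ":rmsd"), {
      tab <- rmsd_table(trj, ann)
      utils::write.csv(tab, file.path(sysdir, "rmsd_table.csv"), row.names = FALSE)
    })
    run_stage(sysdir, paste0(nm, ":rmsf"), {
      heavy <- select_atoms(trj$topology, "heavy")
      prof <- rmsf_profile(trj, heavy, per_residue = TRUE)
      utils::write.csv(data.frame(resno = prof$ids, rmsf = num(prof$values)),
                       file.path(sysdir, "rmsf_heavy.csv"), row.names = FALSE)
    })
    if (!is.null(inp$pairs)) run_stage(sysdir, paste0(nm, ":hbonds"), {
      crit <- hbond_criterion(p$hbond_distance, p$hbond_angle)
      occ <- hbond_occupancy(trj, inp$pairs, crit)
      utils::write.csv(occ, file.path(sysdir, "hbond_occupancy.csv"),
                       row.names = FALSE)
      dst <- distance_stats(trj, data.frame(
        a_resno = inp$pairs$donor_resno, a_name = inp$pairs$donor_name,
        b_resno = inp$pairs$acceptor_resno, b_name = inp$pairs$acceptor_name))
      utils::write.csv(dst, file.path(sysdir, "pair_distances.csv"),
                       row.names = FALSE)
    })
    sel <- run_stage(sysdir, paste0(nm, ":selection"),
                     select_atoms(trj$topology, p$node_selection))
    run_stage(sysdir, paste0(nm, ":pca"), {
      model <- fit_pca(trj, sel)
      npc <- min(p$n_pcs, length(model$values))
      utils::write.csv(data.frame(pc = seq_along(model$values),
                                  eigenvalue = num(model$values),
                                  fraction = num(model$fractional)),
                       file.path(sysdir, "pca_variance.csv"), row.names = FALSE)
      proj <- project(trj, model, pcs = 1:2)
      utils::write.csv(data.frame(frame = seq_len(nrow(proj)),
                                  PC1 = num(proj[, 1]), PC2 = num(proj[, 2]),
                                  cluster = cluster_pc_subspace(proj, k = 2)),
                       file.path(sysdir, "pca_projection.csv"), row.names = FALSE)
      utils::write.csv(data.frame(resno = trj$topology$atom$resno[sel$atom],
                                  rmsf_pc = num(pc_rmsf(model, 1:npc))),
                       file.path(sysdir, "pca_rmsf.csv"), row.names = FALSE)
    })
    net <- run_stage(sysdir, paste0(nm, ":network"), {
      dccm <- compute_dccm(trj, sel)
      write_matrix_csv(unclass(dccm), file.path(sysdir, "dccm.csv"))
      mask <- contact_mask(trj, cutoff = p$contact_cutoff,
                           persistence = p$contact_persistence)
      write_matrix_csv(mask$mask * 1, file.path(sysdir, "contact_mask.csv"))
      net <- build_network(dccm, mask)
      utils::write.csv(edge_list(net), file.path(sysdir, "network_edges.csv"),
                       row.names = FALSE)
      jsonlite::write_json(
        list(labels = net$labels, edges = edge_list(net),
             filter = net$filter),
        file.path(sysdir, "network.json"), auto_unbox = TRUE, digits = NA)
      net
    })
    cent <- run_stage(sysdir, paste0(nm, ":centrality"), {
      tab <- centrality_table(net)
      utils::write.csv(tab, file.path(sysdir, "centrality.csv"), row.names = FALSE)
      tab
    })
    profiles[[nm]] <- cent
    if (!is.null(p$source) && !is.null(p$sink)) {
      run_stage(sysdir, paste0(nm, ":paths"), {
        ens <- yen_k_shortest(net, as.character(p$source),
                              as.character(p$sink), k = p$k_paths)
        if (ens$k_found > 0) {
          utils::write.csv(data.frame(
            path = seq_len(ens$k_found), length = num(ens$lengths),
            nodes = vapply(ens$paths, function(pp)
              paste(ens$labels[pp], collapse = "-"), character(1))),
            file.path(sysdir, "paths.csv"), row.names = FALSE)
          deg <- node_degeneracy(ens)
          utils::write.csv(data.frame(node = names(deg), degeneracy = num(deg)),
                           file.path(sysdir, "degeneracy.csv"), row.names = FALSE)
          npp <- nodes_per_path(ens)
          summ <- path_centrality_summary(
            ens, stats::setNames(cent$betweenness, net$labels),
            stats::setNames(cent$eigenvector, net$labels))
          utils::write.csv(summ, file.path(sysdir, "path_centrality.csv"),
                           row.names = FALSE)
          jsonlite::write_json(
            list(k_requested = ens$k_requested, k_found = ens$k_found,
                 nodes_per_path_mean = npp$mean,
                 nodes_per_path_median = npp$median),
            file.path(sysdir, "paths_summary.json"),
            auto_unbox = TRUE, digits = NA)
        } else {
          jsonlite::write_json(list(k_found = 0, disconnected = TRUE),
                               file.path(sysdir, "paths_summary.json"),
                               auto_unbox = TRUE, digits = NA)
        }
      })
    }
    files <- list.files(sysdir, full.names = TRUE)
    manifest$systems[[nm]] <- list(
      inputs = config$systems[[nm]][c("topology", "trajectory", "annotation", "pairs")],
      synthetic_seed = if (!is.null(inp$spec)) inp$spec$seed else NULL,
      outputs = as.list(stats::setNames(unname(tools::md5sum(files)),
                                        basename(files))))
  }

  if (length(config$comparisons) > 0) {
    rows <- lapply(config$comparisons, function(cmp) {
      a <- profiles[[cmp[1]]]; b <- profiles[[cmp[2]]]
      if (!identical(a$node, b$node))
        stopf("alignment error: systems %s and %s have different node sets",
              cmp[1], cmp[2])
      data.frame(system_a = cmp[1], system_b = cmp[2],
                 sip_betweenness = sip(a$betweenness, b$betweenness),
                 sip_eigenvector = sip(a$eigenvector, b$eigenvector))
    })
    cmp_tab <- do.call(rbind, rows)
    utils::write.csv(cmp_tab, file.path(outdir, "comparisons.csv"),
                     row.names = FALSE)
    manifest$comparisons <- cmp_tab
  }

  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}

#' Compare two pipeline output bundles
#'
#' Reads the per-system outputs of [run_pipeline()] for two states and emits
#' the comparison a two-state study reports: SIP between centrality profiles,
#' per-node centrality deltas (b minus a), degeneracy overlay, and the DCCM
#' difference matrix.
#'
#' @param dir_a,dir_b per-system output directories from [run_pipeline()].
#' @param outdir optional directory for comparison CSVs.
#' @return list with `sip_betweenness`, `sip_eigenvector`, `deltas`
#'   (data.frame), `degeneracy` (data.frame or NULL), `dccm_difference`
#'   (matrix).
#' @export
compare_states <- function(dir_a, dir_b, outdir = NULL) {
  ca <- utils::read.csv(file.path(dir_a, "centrality.csv"))
  cb <- utils::read.csv(file.path(dir_b, "centrality.csv"))
  if (!identical(as.character(ca$node), as.character(cb$node)))
    stopf("alignment error: node sets differ between bundles")
  deltas <- data.frame(node = ca$node,
                       d_betweenness = cb$betweenness - ca$betweenness,
                       d_eigenvector = cb$eigenvector - ca$eigenvector)
  da <- file.path(dir_a, "degeneracy.csv"); db <- file.path(dir_b, "degeneracy.csv")
  degeneracy <- if (file.exists(da) && file.exists(db)) {
    ga <- utils::read.csv(da); gb <- utils::read.csv(db)
    merge(stats::setNames(ga, c("node", "degeneracy_a")),
          stats::setNames(gb, c("node", "degeneracy_b")), by = "node",
          all = TRUE)
  }
  Ca <- read_matrix_csv(file.path(dir_a, "dccm.csv"))
  Cb <- read_matrix_csv(file.path(dir_b, "dccm.csv"))
  if (!identical(dim(Ca), dim(Cb)))
    stopf("alignment error: DCCM dimensions differ")
  out <- list(sip_betweenness = sip(ca$betweenness, cb$betweenness),
              sip_eigenvector = sip(ca$eigenvector, cb$eigenvector),
              deltas = deltas, degeneracy = degeneracy,
              dccm_difference = Cb - Ca)
  if (!is.null(outdir)) {
    dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
    utils::write.csv(deltas, file.path(outdir, "centrality_deltas.csv"),
                     row.names = FALSE)
    if (!is.null(degeneracy))
      utils::write.csv(degeneracy, file.path(outdir, "degeneracy_overlay.csv"),
                       row.names = FALSE)
    write_matrix_csv(out$dccm_difference, file.path(outdir, "dccm_difference.csv"))
    jsonlite::write_json(list(sip_betweenness = out$sip_betweenness,
                              sip_eigenvector = out$sip_eigenvector),
                         file.path(outdir, "sip.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  out
}
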