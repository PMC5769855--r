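#' Configuration for a full clique-and-cavity analysis
#'
#' Validates inputs for [run_full_analysis()]. All referenced paths must
#' exist at validation time; seeds and parameters are recorded in the output
#' manifest so every file is regenerable from the manifest alone.
#'
#' @param input Character vector of network matrix paths (averaged
#'   element-wise when more than one).
#' @param out_dir Output directory (created if absent).
#' @param metadata Optional node metadata path.
#' @param coords Optional node-coordinate table path (columns x, y, z);
#'   enables the minimally wired null model.
#' @param scans Optional character vector of scan network paths for cavity
#'   matching.
#' @param rho Edge density threshold (default 0.25).
#' @param max_dim Maximum homology dimension (default 2).
#' @param tiebreak `"deterministic"` (lexicographic) or `"noise"` (seeded
#'   uniform noise bounded by `noise_epsilon`).
#' @param noise_epsilon Tie-break noise bound (default 1e-4).
#' @param seed Integer seed recorded and used for all randomness.
#' @param n_null Rewired nulls for the rich club (default 1000).
#' @param richclub Compute the rich club? Default `TRUE`.
#' @param betti Write Betti curves? Default `TRUE`.
#' @param top_k How many longest-lived classes get minimal-cycle recovery.
#' @return A `run_config` list.
#' @export
run_config <- function(input, out_dir, metadata = NULL, coords = NULL,
                       scans = character(), rho = 0.25, max_dim = 2L,
                       tiebreak = c("deterministic", "noise"),
                       noise_epsilon = 1e-4, seed = 1L, n_null = 1000L,
                       richclub = TRUE, betti = TRUE, top_k = 4L) {
  tiebreak <- match.arg(tiebreak)
  paths <- c(input, metadata, coords, scans)
  missing <- paths[!file.exists(paths)]
  if (length(missing)) {
    abort(paste0("missing input file(s): ", paste(missing, collapse = ", ")))
  }
  stopifnot(rho >= 0, rho <= 1, max_dim >= 1, n_null >= 2, top_k >= 0)
  structure(
    list(
      input = input, metadata = metadata, coords = coords, scans = scans,
      out_dir = out_dir, rho = rho, max_dim = as.integer(max_dim),
      tiebreak = tiebreak, noise_epsilon = noise_epsilon,
      seed = as.integer(seed), n_null = as.integer(n_null),
      richclub = isTRUE(richclub), betti = isTRUE(betti),
      top_k = as.integer(top_k)
    ),
    class = "run_config"
  )
}

#' Read a run configuration from a key = value file
#'
#' Flat text format: one `key = value` per line, `#` comments, commas
#' separating multiple paths for `input` and `scans`.
#'
#' @param path Config file path.
#' @return A [run_config()].
#' @export
read_run_config <- function(path) {
  lines <- readLines(path)
  lines <- trimws(sub("#.*", "", lines))
  lines <- lines[nzchar(lines)]
  kv <- strsplit(lines, "=", fixed = TRUE)
  keys <- trimws(vapply(kv, `[`, "", 1))
  vals <- trimws(vapply(kv, function(x) paste(x[-1], collapse = "="), ""))
  cfg <- setNames(as.list(vals), keys)
  split_paths <- function(x) if (is.null(x)) NULL else trimws(strsplit(x, ",")[[1]])
  num <- function(x, d) if (is.null(x)) d else as.numeric(x)
  run_config(
    input = split_paths(cfg$input),
    out_dir = cfg$out_dir,
    metadata = cfg$metadata,
    coords = cfg$coords,
    scans = split_paths(cfg$scans) %||% character(),
    rho = num(cfg$rho, 0.25),
    max_dim = num(cfg$max_dim, 2),
    tiebreak = cfg$tiebreak %||% "deterministic",
    noise_epsilon = num(cfg$noise_epsilon, 1e-4),
    seed = num(cfg$seed, 1),
    n_null = num(cfg$n_null, 1000),
    richclub = !identical(cfg$richclub, "false"),
    betti = !identical(cfg$betti, "false"),
    top_k = num(cfg$top_k, 4)
  )
}

diagram_to_table <- function(dgm, node_ids) {
  fmt <- function(col) vapply(
    col, function(s) paste(node_ids[s], collapse = " "), character(1)
  )
  tibble(
    dimension = dgm$dimension,
    birth_step = dgm$birth_step,
    death_step = dgm$death_step,
    rho_birth = dgm$rho_birth,
    rho_death = dgm$rho_death,
    lifetime = dgm$lifetime,
    pi = dgm$pi,
    birth_simplex = fmt(dgm$birth_simplex)
  )
}

#' Run the full clique-and-cavity analysis
#'
#' Orchestrates load/average -> threshold -> maximal cliques and
#' participation -> communicability, rich club, cores -> weight rank clique
#' filtration and persistence (with Betti curves) -> minimal cycle recovery
#' for the longest-lived classes -> minimally wired null comparison ->
#' per-scan cavity matching. Writes delimited tables plus a JSON manifest
#' listing every file with the parameters, seeds, and input fingerprints
#' that produced it; identical configs and seeds yield byte-identical
#' numeric outputs. Any stage error aborts with the stage name.
#'
#' @param config A [run_config()] or path to a config file.
#' @return The manifest, invisibly (a list).
#' @export
run_full_analysis <- function(config) {
  if (is.character(config)) config <- read_run_config(config)
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  files <- character(0)
  current_stage <- "setup"
  stage <- function(name) current_stage <<- name
  emit <- function(df, name) {
    p <- file.path(config$out_dir, name)
    readr::write_tsv(df, p, progress = FALSE)
    files <<- c(files, p)
    p
  }
  withCallingHandlers(
    {
      stage("load")
      nets <- lapply(config$input, read_network,
                     metadata_path = config$metadata)
      avg <- group_average(nets)
      if (config$tiebreak == "noise") {
        avg <- add_tiebreak_noise(avg, config$noise_epsilon, config$seed)
      }
      stage("threshold")
      thr <- threshold_by_density(avg, config$rho, ties = "lexicographic")
      emit(
        tibble(rho = config$rho, retained_edges = attr(thr, "retained_edges")),
        "threshold.tsv"
      )
      stage("cliques")
      mc <- maximal_cliques(thr)
      part <- node_participation(mc, n_nodes(avg), avg$node_ids)
      emit(
        tibble(clique = mc$clique, k = mc$k,
               nodes = vapply(mc$node_ids, paste, "", collapse = " ")),
        "maximal_cliques.tsv"
      )
      emit(part, "participation.tsv")
      emit(clique_degree_distribution(mc), "clique_degrees.tsv")
      stage("graph_stats")
      node_tab <- core_decomposition(avg)
      if (all(node_strength(avg) > 0)) {
        node_tab$communicability <- communicability(avg)$node$communicability
      }
      emit(node_tab, "node_stats.tsv")
      if (config$richclub) {
        rc <- rich_club(avg, n_null = config$n_null, seed = config$seed)
        emit(as_tibble(rc), "rich_club.tsv")
      }
      stage("persistence")
      filt <- build_filtration(avg)
      dgm <- persistent_homology(filt, max_dim = config$max_dim)
      emit(diagram_to_table(dgm, avg$node_ids), "diagram_empirical.tsv")
      if (config$betti) {
        emit(betti_curves(filt, max_dim = config$max_dim), "betti_curves.tsv")
      }
      stage("minimal_cycles")
      finite <- dgm[is.finite(dgm$rho_death), ]
      finite <- finite[order(-finite$lifetime), ]
      top <- head(finite, config$top_k)
      reps_list <- list()
      if (nrow(top)) {
        cyc_rows <- lapply(seq_len(nrow(top)), function(ii) {
          pt <- top[ii, ]
          reps <- if (pt$dimension == 1) {
            minimal_1cycles(filt, pt)
          } else {
            minimal_2cycles(filt, pt)
          }
          reps_list[[ii]] <<- reps
          tibble(
            class = ii,
            dimension = pt$dimension,
            rho_birth = pt$rho_birth,
            rho_death = pt$rho_death,
            representative = seq_len(nrow(reps)),
            equivalence_class = reps$class_id,
            n_nodes = reps$n_nodes,
            nodes = vapply(reps$nodes,
                           function(v) paste(avg$node_ids[v], collapse = " "), ""),
            cliques = vapply(reps$cliques, function(m) {
              paste(apply(m, 1, function(r) {
                paste(avg$node_ids[r], collapse = "-")
              }), collapse = "; ")
            }, "")
          )
        })
        emit(bind_rows(cyc_rows), "minimal_cycles.tsv")
      }
      stage("null_model")
      if (!is.null(config$coords)) {
        ctab <- readr::read_csv(config$coords, show_col_types = FALSE,
                                progress = FALSE)
        mw <- minimally_wired(as.matrix(ctab[, c("x", "y", "z")]),
                              node_ids = avg$node_ids)
        mw_thr <- threshold_by_density(mw, config$rho, ties = "lexicographic")
        mw_dgm <- persistent_homology(build_filtration(mw),
                                      max_dim = config$max_dim)
        emit(diagram_to_table(mw_dgm, avg$node_ids), "diagram_null.tsv")
        mw_part <- node_participation(maximal_cliques(mw_thr), n_nodes(avg),
                                      avg$node_ids)
        emit(mw_part, "participation_null.tsv")
      }
      stage("matching")
      if (length(config$scans) && length(reps_list)) {
        scans <- lapply(config$scans, read_network)
        match_rows <- lapply(seq_along(reps_list), function(ii) {
          mres <- match_cavities(reps_list[[ii]], scans,
                                 scan_ids = basename(config$scans))
          mutate(mres, class = ii, .before = 1)
        })
        emit(bind_rows(match_rows), "match.tsv")
      }
      stage("manifest")
      manifest <- list(
        package = "cliquecavity",
        parameters = config[c("rho", "max_dim", "tiebreak", "noise_epsilon",
                              "n_null", "top_k", "richclub", "betti")],
        seed = config$seed,
        inputs = lapply(
          stats::setNames(nm = c(config$input, config$scans)),
          function(p) unname(tools::md5sum(p))
        ),
        outputs = lapply(
          stats::setNames(files, basename(files)),
          function(p) unname(tools::md5sum(p))
        )
      )
      jsonlite::write_json(
        manifest, file.path(config$out_dir, "manifest.json"),
        auto_unbox = TRUE, pretty = TRUE
      )
      invisible(manifest)
    },
    error = function(e) {
      abort(
        sprintf("stage '%s' failed: %s", current_stage, conditionMessage(e)),
        parent = e
      )
    }
  )
}
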