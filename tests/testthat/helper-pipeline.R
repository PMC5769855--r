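write_fixture_inputs <- function(dir) {
  po <- planted_octahedron()
  net_path <- file.path(dir, "octahedron.csv")
  write_network(po$network, net_path)
  coords <- withr::with_seed(2, matrix(runif(18), 6, 3))
  coords_path <- file.path(dir, "coords.csv")
  readr::write_csv(
    tibble::tibble(x = coords[, 1], y = coords[, 2], z = coords[, 3]),
    coords_path
  )
  scans <- perturb_scans(po$network, 2, weight_jitter = 0.03, seed = 5)
  scan_paths <- file.path(dir, c("scan1.csv", "scan2.csv"))
  for (ii in 1:2) write_network(scans[[ii]], scan_paths[ii])
  list(net = net_path, coords = coords_path, scans = scan_paths)
}

pipeline_config <- function(paths, out_dir, seed = 1) {
  run_config(
    input = paths$net, out_dir = out_dir, coords = paths$coords,
    scans = paths$scans, rho = 0.8, n_null = 5, seed = seed, top_k = 1
  )
}
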