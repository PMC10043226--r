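library(epinetsim)
tryrun <- function(n, nf, spec, scale, sg, seed, dt = 0.05) {
  base <- build_base_network(n); base$global_scale <- scale
  fadj <- build_focal_adjacency(spec, seed = seed)
  S <- embed_focal(base, fadj, 1:nf, K = 10)
  prof <- sample_x0(n, 1:nf, mu = -1.6, sigma = sg, seed = seed + 7)
  r <- try(simulate_network(S, prof, cfg = network_run_config(seed = seed + 13, dt = dt)), silent = TRUE)
  if (inherits(r, "try-error")) return(paste("FAIL:", attr(r, "condition")$message))
  cm <- correlation_matrix(r$z)
  sprintf("ok deg=%.3f", average_degree(threshold_top_fraction(cm, .275), 1:nf))
}
cat("p0 n100 scale0.5:", tryrun(100, 20, focal_topology(20,"regular",k=4), 0.5, 0, 501), "\n")
cat("sf22 n100 scale0.5:", tryrun(100, 20, focal_topology(20,"scalefree",gamma_sf=2.2,k=4), 0.5, 0, 503), "\n")
cat("sf22 n100 scale0.25:", tryrun(100, 20, focal_topology(20,"scalefree",gamma_sf=2.2,k=4), 0.25, 0, 503), "\n")
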