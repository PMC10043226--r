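library(epinetsim)
cell <- function(n, nf, spec, scale, sg, r) {
  base <- build_base_network(n); base$global_scale <- scale
  fadj <- build_focal_adjacency(spec, seed = 500 + r)
  S <- embed_focal(base, fadj, 1:nf, K = 10)
  prof <- sample_x0(n, 1:nf, mu = -1.6, sigma = sg, seed = 9000 + 100*r + round(1000*sg))
  tr <- simulate_network(S, prof, cfg = network_run_config(seed = 300 + r))
  average_degree(threshold_top_fraction(correlation_matrix(tr$z), .275), 1:nf)
}
n <- 40; nf <- 8
for (scale in c(0.2, 0.3, 0.4)) {
  for (fam in c("sf22", "p0")) {
    spec <- if (fam == "sf22") focal_topology(nf,"scalefree",gamma_sf=2.2,k=4) else focal_topology(nf,"regular",k=4)
    m <- sapply(c(0, 0.15), function(sg) mean(sapply(1:4, function(r) cell(n, nf, spec, scale, sg, r))))
    cat(sprintf("scale %.2f %s: sg0=%.3f sg.15=%.3f\n", scale, fam, m[1], m[2]))
  }
}
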