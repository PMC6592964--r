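# Shared fixtures, built in code.  Spherical lead fields are cached per test
# run since every module exercises the same 19-channel three-shell model.

.fixture_cache <- new.env(parent = emptyenv())

random_leadfield <- function(nc, ns, seed = 1) {
  set.seed(seed)
  matrix(rnorm(nc * ns), nc, ns)
}

montage19 <- function() {
  if (is.null(.fixture_cache$m19)) .fixture_cache$m19 <- montage_1020()
  .fixture_cache$m19
}

spherical_K <- function(n_sources = 300) {
  key <- paste0("sph", n_sources)
  if (is.null(.fixture_cache[[key]])) {
    .fixture_cache[[key]] <- spherical_leadfield(montage19(),
                                                 source_grid(n_sources))
  }
  .fixture_cache[[key]]
}

# The four-member UR family on n channels (REST needs a lead field).
ur_family <- function(n, K, anchors_rr = 1L, anchors_lm = NULL) {
  if (is.null(anchors_lm)) anchors_lm <- c(1L, min(2L, n))
  list(RR = ur_weights("RR", n_channels = n, anchors = anchors_rr),
       LM = ur_weights("LM", n_channels = n, anchors = anchors_lm),
       AR = ur_weights("AR", n_channels = n),
       REST = rest_weights(K))
}

t_ar <- function(n) diag(n) - matrix(1 / n, n, n)

rel_err <- function(est, truth) {
  sqrt(sum((est - truth)^2)) / sqrt(sum(truth^2))
}
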