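# Small hand-built networks and configurations for engine-level tests.

# Construct a minimal nk_network-compatible object from explicit pieces.
test_network <- function(species, reactions, geom, moieties = NULL) {
  n_sp <- nrow(species)
  species$hop_rate <- species$D / (geom$l0 * 1e-3)^2
  if (is.null(species$phospho_vav)) species$phospho_vav <- FALSE
  n_rx <- length(reactions)
  stoich <- matrix(0L, n_sp, n_rx, dimnames = list(species$name, NULL))
  reactant_idx <- vector("list", n_rx)
  prop <- numeric(n_rx)
  for (j in seq_len(n_rx)) {
    r <- reactions[[j]]
    reactant_idx[[j]] <- match(r$reactants, species$name)
    for (x in r$reactants) stoich[x, j] <- stoich[x, j] - 1L
    for (x in r$products) stoich[x, j] <- stoich[x, j] + 1L
    prop[j] <- r$propensity
  }
  if (is.null(moieties))
    moieties <- diag(n_sp)
  dimnames(moieties) <- list(species$name, NULL)
  net <- list(species = species,
              reactions = data.frame(propensity = prop),
              stoich = stoich, reactant_idx = reactant_idx,
              moieties = moieties, counts = list(), geom = geom)
  class(net) <- "nk_network"
  net
}

# A bare configuration with all molecules of each species in given chambers.
test_config <- function(network, counts_matrix,
                        mask_a = NULL, mask_k = NULL) {
  geom <- network$geom
  if (is.null(mask_a)) mask_a <- integer(geom$n_chambers)
  if (is.null(mask_k)) mask_k <- integer(geom$n_chambers)
  colnames(counts_matrix) <- network$species$name
  structure(list(counts = counts_matrix, mask_nkg2d = mask_a,
                 mask_kir = mask_k, mode = "homogeneous", seed = NULL,
                 pruned = c(nkg2d = NA_real_, kir = NA_real_),
                 clusters = list(), coms = list(), geom = geom),
            class = "nk_config")
}

free_species_df <- function(names, D) {
  data.frame(name = names, compartment = "NK-membrane", D = D,
             confinement = "none", phospho_vav = FALSE,
             stringsAsFactors = FALSE)
}

# matrix with class/attribute decoration stripped
bare <- function(m) matrix(as.vector(unclass(m)), nrow(m))

# cached full network for tests that need the real model
default_net <- local({
  net <- NULL
  function() {
    if (is.null(net)) net <<- build_network()
    net
  }
})
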