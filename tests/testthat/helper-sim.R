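# Shared simulation scenarios. Sizes are chosen to keep the default test run
# fast while leaving enough signal for the recovery checks.

# one WGD on species A's branch after the A/B split
simOneWgd <- function(seed, nFamilies = 150, ageKs = 1.0, retention = 0.3,
                      cdsCodons = 300) {
  cfg <- simConfig("(A:0.75,B:0.75);",
                   wgdEvents = data.frame(branch = "A", age_ks = ageKs,
                                          retention = retention),
                   nFamilies = nFamilies, genesPerScaffold = 25,
                   cdsCodons = cdsCodons, seed = seed)
  simulateDataset(cfg)
}

# three ingroup species + outgroup, WGD on the ingroup stem branch
simStemWgd <- function(seed, nFamilies = 40, ageKs = 0.9, retention = 0.3,
                       cdsCodons = 200) {
  cfg <- simConfig("(((B:0.15,C:0.15):0.15,A:0.3):0.3,O:0.6);",
                   wgdEvents = data.frame(branch = "A|B|C", age_ks = ageKs,
                                          retention = retention),
                   nFamilies = nFamilies, genesPerScaffold = 20,
                   cdsCodons = cdsCodons, seed = seed)
  simulateDataset(cfg)
}

speciesHomology <- function(sim, spA, spB = NULL) {
  gA <- geneTable(sim$genomes[[spA]])$gene_id
  h <- sim$homology
  if (is.null(spB)) return(h[h$gene_a %in% gA & h$gene_b %in% gA, , drop = FALSE])
  gB <- geneTable(sim$genomes[[spB]])$gene_id
  h[h$gene_a %in% gA & h$gene_b %in% gB, , drop = FALSE]
}

geneSpeciesMap <- function(sim) {
  with(truthGenes(sim$truth), stats::setNames(species, gene_id))
}
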