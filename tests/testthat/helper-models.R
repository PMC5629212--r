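# Fixture builders shared across the suite. All data are generated in code.

# A -> P1 -> P2 chain with an unrelated third marker
chainModel3 <- function(aS = 1, bTS = 0.8) {
  B <- matrix(0, 3, 3)
  B[2, 1] <- bTS
  causalModel(B, a = c(aS, 0, 0))
}

# no effects at all: B = 0, a = 0
nullModel3 <- function() {
  causalModel(matrix(0, 3, 3), a = c(0, 0, 0))
}

# A -> P1, P1 <- H -> P2 (latent confounder), no directed P1-P2 edge
confounderModel3 <- function(load = 0.9) {
  lam <- c(load, load, 0)
  causalModel(matrix(0, 3, 3), diag(3) + lam %o% lam, a = c(1, 0, 0))
}

# dose-zero-only replicate study for CLCD
replicateStudy <- function(model, seed, nReps = 27, n = 1000) {
  design <- makeStudyDesign(model, nActivators = 1, nInhibitors = nReps,
                            nDosages = 1, nPerCondition = n, seed = seed)
  simulateStudy(model, design, seed = seed)
}

# per-environment cell matrices for a model under given intervention designs
environmentTables <- function(model, ivList, n, seed) {
  lapply(seq_along(ivList), function(e)
    cellValues(simulateCondition(model, ivList[[e]], n = n,
                                 seed = seed * 100 + e)))
}

# acyclic 3-marker reference model for connectivity estimation
acyclicModel3 <- function() {
  B <- matrix(0, 3, 3)
  B[2, 1] <- 0.7
  B[3, 2] <- -0.5
  B[3, 1] <- 0.4
  causalModel(B)
}

# intervention-variance profiles with pairwise non-proportional centered
# patterns (the identifiability condition for shift interventions)
threeEnvDesign <- function() {
  list(c(0, 0, 0), c(5, 0.1, 1), c(0.1, 5, 2.5))
}

# pooled A/S/T trio table from an explicit generating mechanism
trioTable <- function(n, aS = 1, bTS = 0.8, seed = 1) {
  set.seed(seed)
  A <- rep(0:1, each = n / 2)
  S <- aS * A + rnorm(n)
  T <- bTS * S + rnorm(n)
  data.frame(A = A, S = S, T = T)
}

# hand-built minimal KGML with two activation relations X -> Y -> Z
writeKGMLFixture <- function(path) {
  writeLines(c(
    '<?xml version="1.0"?>',
    '<pathway name="path:test01" title="synthetic three-node pathway">',
    '  <entry id="1" name="hsa:111" type="gene">',
    '    <graphics name="X, X-alias"/>',
    '  </entry>',
    '  <entry id="2" name="hsa:222" type="gene">',
    '    <graphics name="Y"/>',
    '  </entry>',
    '  <entry id="3" name="hsa:333" type="gene">',
    '    <graphics name="Z"/>',
    '  </entry>',
    '  <relation entry1="1" entry2="2" type="PPrel">',
    '    <subtype name="activation" value="--&gt;"/>',
    '  </relation>',
    '  <relation entry1="2" entry2="3" type="PPrel">',
    '    <subtype name="phosphorylation" value="+p"/>',
    '  </relation>',
    '</pathway>'), path)
  path
}
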