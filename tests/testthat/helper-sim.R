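# Simulations are the expensive fixture; build each configuration once
# per test run and share it across test files.
.simCache <- new.env(parent = emptyenv())

cachedSim <- function(key, cfg) {
  if (is.null(.simCache[[key]]))
    .simCache[[key]] <- simulateLines(cfg)
  .simCache[[key]]
}

# desk-scale sweep replicate: default study conditions plus one
# large-effect QTL mid-chromosome 1
sweepSimConfig <- function(seed)
  simConfig(seed = seed,
            qtl = data.frame(chrom = 1, pos_bp = 6e6, effect = 2.5))

sweepSim <- function(seed = 101L)
  cachedSim(paste0("sweep", seed), sweepSimConfig(seed))

neutralSim <- function(seed = 201L)
  cachedSim(paste0("neutral", seed), simConfig(seed = seed))

# ids of one line
lineIds <- function(lines, label) names(lineOf(lines))[lineOf(lines) == label]
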