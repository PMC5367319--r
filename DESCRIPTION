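Package: parapatric
Title: Stochastic Models of Parapatric Speciation on Two and Three Islands
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Simulates the accumulation of genetic incompatibilities between
    island populations connected by rare migration. Incompatibility is carried
    by l unlinked loci; populations are effectively monomorphic, novel alleles
    fix at rate u per locus per island, and successful migration events arrive
    as a Poisson process, after which each differing locus fixes the migrant
    allele with probability eps. For two islands the genetic distance z follows
    a one-dimensional stochastic differential equation; for three islands the
    package tracks the five geographical configurations of allele sharing
    (ABC), (A)(BC), (B)(CA), (C)(AB), (A)(B)(C), whose fractions obey a
    five-dimensional SDE with bond-shared migration noise. Speciation occurs
    when the migration graph of islands disconnects (pairwise distance above a
    threshold z_c closes a bond). Includes an exact per-locus jump-process
    simulator used as ground truth for the diffusion approximation, and batch
    drivers for waiting-time experiments (threshold sweeps, fixed m*eps sweeps,
    and the tau3/tau2 ratio versus migration-rate heterogeneity).
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    graphics,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
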