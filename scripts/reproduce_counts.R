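#!/usr/bin/env Rscript
# Opt-in reproduction of the published example counts (152 positive /
# 5345 negative pairs) from locally downloaded copies of the WI-PHI
# weighted interaction table and the CYC2008 complex catalog.  Both
# files must be converted to the package's TSV projections first:
#   network: protein_a TAB protein_b TAB ... weight (wi-phi dialect)
#   catalog: complex_id TAB protein (one row per membership)
#
# Usage:
#   Rscript scripts/reproduce_counts.R <wiphi.tsv> <cyc2008.tsv>
#
# This is deliberately a standalone script, not a test: it needs
# external downloads and identifier curation that the desk-scale suite
# does not assume.

suppressPackageStartupMessages(library(pairkern))

args <- commandArgs(trailingOnly = TRUE)
if (length(args) != 2L) {
  stop("usage: reproduce_counts.R <wiphi.tsv> <cyc2008.tsv>")
}
net <- read_weighted_ppi(args[1L], dialect = "wi-phi")
catalog <- read_complex_catalog(args[2L])
pairs <- build_examples(net, catalog)
cat(sprintf("network: %d proteins\npositives: %d (published: 152)\nnegatives: %d (published: 5345)\n",
            length(net$proteins), sum(pairs$label == 1L),
            sum(pairs$label == -1L)))
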