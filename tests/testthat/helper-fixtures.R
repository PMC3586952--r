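# Shared fixtures: compact taxon samplings keep single tests fast while the
# acceptance suite exercises the full reference sampling.

small_group_sizes <- function() {
  c(Outgroup = 2L, Microsporidia = 3L, Chytridiomycotina = 1L,
    Zygomycotina = 2L, Basidiomycotina = 1L, Taphrinomycotina = 1L,
    Saccharomycotina = 1L, Pezizomycotina = 1L)
}

# A colinear toy genome: nGenes genes on one contig, all "+", families
# f01.., orthologs og01..; a clone with a different genome id shares both
# namespaces.
colinear_genome <- function(id, nGenes, strand = "+") {
  GeneOrderGenome(id, data.frame(
    gene_id = sprintf("%s_g%02d", id, seq_len(nGenes)),
    contig = "c1", index = seq_len(nGenes) - 1L,
    strand = rep(strand, nGenes),
    family_id = sprintf("f%02d", seq_len(nGenes)),
    ortholog_id = sprintf("og%02d", seq_len(nGenes)),
    stringsAsFactors = FALSE))
}

unrooted_quartet_long_o2 <- function() {
  ape::read.tree(text = "((f1__g1:0.1,f2__g1:0.1):0.1,(o1__g1:0.1,o2__g1:1.0):0.1);")
}
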