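#!/usr/bin/env Rscript
# Cross-assay hit intersection on the demonstration screen: build the
# screen-enriched hit set (L > 1), synthesize two differential-expression
# tables (an in vivo-like and an in vitro-like assay) whose upregulated
# genes partially overlap the planted protective knockouts, and report
# the exact Venn regions. DE tables here are synthetic stand-ins: real
# runs consume DE TSVs (gene, log2fc, padj) from external scRNA-seq
# analyses. Writes results/demo/venn.{tsv,json}.

suppressMessages(library(isletscreen))

outdir <- "results/demo"
if (!file.exists(file.path(outdir, "results.tsv"))) {
  stop("run analysis/02_screen_statistics.R first")
}
ranked <- as.data.frame(readr::read_tsv(file.path(outdir, "results.tsv"),
                                        show_col_types = FALSE))
screen_hits <- filter_screen_enriched(ranked, lfc_min = 1,
                                      name = "screen")
message(sprintf("screen-enriched set (L > 1): %d genes",
                length(screen_hits$genes)))

# synthetic DE tables: upregulated sets overlapping the screen's top genes
set.seed(20260929)
top <- utils::head(ranked$gene, 30)
make_de <- function(up_genes, decoys) {
  data.frame(gene = c(up_genes, decoys),
             log2fc = c(runif(length(up_genes), 1.2, 4),
                        runif(length(decoys), -1, 0.9)),
             padj = c(runif(length(up_genes), 1e-6, 0.04),
                      runif(length(decoys), 0, 1)))
}
de_invivo <- make_de(sample(top, 15), sprintf("DECOY%03d", 1:50))
de_invitro <- make_de(sample(top, 12), sprintf("DECOY%03d", 26:75))
dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
readr::write_tsv(de_invivo, file.path(outdir, "de_invivo_synthetic.tsv"))
readr::write_tsv(de_invitro, file.path(outdir, "de_invitro_synthetic.tsv"))

sets <- list(
  filter_de_up(de_invivo, name = "invivo_DE"),
  filter_de_up(de_invitro, name = "invitro_DE"),
  screen_hits
)
v <- venn(sets)
write_venn(v, file.path(outdir, "venn.tsv"), file.path(outdir, "venn.json"))

message("Venn regions (pattern: invivo_DE / invitro_DE / screen):")
print(v[, c("region", "count")], row.names = FALSE)
core <- v$genes[v$invivo_DE & v$invitro_DE & v$screen]
message("genes supported by all three assays: ",
        if (nzchar(core)) core else "(none)")
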