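Package: cyclepeaks
Title: Rank-Based Detection of Cell-Cycle Periodic Transcripts and
    Drug-Sensitivity-Related Isoforms
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Detects transcripts periodically expressed across a
    synchronized cell-cycle time course using a reference-free,
    rank-based circular peak-calling algorithm operating on ordered
    FPKM matrices. Maps expression peaks to cell-cycle phases, orders
    transcripts for heatmap display, and intersects periodic calls
    across cell lines under a same-or-adjacent-phase rule. Also
    provides a pharmaco-transcriptomic scan that correlates drug IC50
    values with target-gene and transcript-isoform expression across
    cell-line panels (Spearman) and flags isoforms whose absolute
    correlation exceeds that of their parent gene by at least 0.1,
    optionally stratified by tissue. Includes a synthetic-data
    generator producing circular-bump time courses and isoform-driven
    drug-response panels with ground truth, and a command-line entry
    point wiring the detect, common, drugcorr and simulate subcommands.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
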