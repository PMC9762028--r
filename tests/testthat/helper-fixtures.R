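# Shared in-code fixtures.

fixture_three_transcripts <- function() {
  # ramp passes part 1; spike fails both rank screens; constant always fails
  m <- rbind(ramp = 1:8,
             spike = c(0, 0, 0, 10, 0, 0, 0, 0),
             flat = rep(5, 8))
  colnames(m) <- paste0("s", 1:8)
  m
}

fixture_hct116_panel <- function() {
  # 8 harvests after G1/S release spanning one cycle
  data.frame(sample = paste0("s", 1:8),
             time_h = c(0, 3, 7, 8, 9, 10, 11, 13),
             phase = c("G1/S", "S", "S", "G2/M", "G2/M", "G2/M", "M-G1", "M-G1"),
             stringsAsFactors = FALSE)
}

write_fixture_tsv <- function(lines) {
  path <- tempfile(fileext = ".tsv")
  writeLines(lines, path)
  path
}
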