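# shared toy layouts

small_layout <- function(windowSize = 1e4,
                         autosome = 8e5, z = 1.5e5, w = 5e4) {
  GenomeLayout(data.frame(
    name = c("chr1", "chrZ", "chrW"),
    class = c("autosome", "Z", "W"),
    length = c(autosome, z, w)), windowSize = windowSize)
}
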