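Package: pr19scan
Title: Detection and Characterisation of piRNA-Related 19-nt RNAs in Small
    RNA Sequencing Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for identifying and characterising piRNA-related 19-nt
    RNAs (pr19RNAs) in small RNA sequencing libraries from mouse testis.
    Implements read filtering, an exact/mismatch-tolerant short-read mapper
    for repeat consensus references, motif-based classification of reads
    into pr19RNA, primary piRNA and secondary piRNA classes from internal
    and flanking bases, ping-pong signature analytics (sequence logos by
    Shannon information, 5'-end offset densities, adjacency-configuration
    counting), genome-wide annotation of 19mers by the tenth downstream
    base and prioritised feature tracks, 2.5 kb genome tiling with paired
    Wilcoxon comparison of pr19RNA and secondary piRNA abundance, and a
    fully seeded synthetic ping-pong read simulator providing ground truth
    for every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
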