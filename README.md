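# loopSplice

Quantifies **co-transcriptional splicing delay** on microscopically
resolvable transcription loops — highly expressed genes whose axis extends
micrometres into the nucleoplasm, decorated with nascent transcripts. On
such a loop, an RNA-FISH probe against one intron labels exactly the
stretch of the gene axis over which nascent RNAs still carry that intron.
If splicing lags a distance *d* (kb) behind the elongating polymerase, the
probe marks the interval

    [intron_start, min(intron_end + 1000*d, gene_end))

instead of the intron alone, and the disproportion between the segmented
intron volume and a whole-gene (BAC) probe volume measures the delay. The
package is aimed at microscopists and genomicists who want this analysis
chain as tested, scriptable R functions rather than one-off scripts.

## What it implements

* **Synthetic data with ground truth** — multi-channel 3D confocal stacks
  of nuclei carrying worm-like-chain transcription loops with per-allele
  transcriptional bursting, four-colour bead calibration fields, and
  nascent long reads drawn from a per-intron delay model
  (`simulateLoopStack`, `simulateBeadStack`, `simulateReads`).
* **Chromatic registration** — bead centroid detection, per-channel shift
  estimation (median of matched centroid displacements) and subvoxel
  trilinear correction (`detectBeads`, `estimateShift`, `applyShift`).
* **Segmentation** — Otsu thresholding (`otsuThreshold`), nucleus
  segmentation with marker-controlled 3D watershed separation and
  border-object removal (`segmentNucleus`), and FISH-signal segmentation
  with local-entropy pre-masking, keeping at most the two largest objects
  per channel (`segmentFish`).
* **Colocalization statistics** — the overlap ratio
  `V_overlap / (V_intron + V_BAC)` (bounded by 0.5) with the 80%
  containment QC rule, the expected genomic-length ratio
  (`expectedOverlap`), and the masked 3D pixel-wise Pearson correlation
  after Gaussian smoothing with sigma = 1 voxel (`pccMask`, `pcc`).
* **Long-read intron calls** — per-intron classification of spliced
  alignments into spliced / unspliced / incomplete / ambiguous,
  intron-containing read selection, 300-nt read-length histograms,
  introns-per-read distributions, per-intron coverage and delay-distance
  estimation (`classifyReads`, `intronContainingReads`, `estimateDelay`),
  plus elongation-time arithmetic (`transcriptionTime`).
* **Group statistics** — boxplot five-number summaries with 1.5 x IQR
  whiskers and one-way ANOVA with Tukey HSD (`summarizeBox`,
  `anovaTukey`).
* **Pipelines** — end-to-end experiments from a YAML/list config with
  tidy per-nucleus or per-read tables, QC logging and CSV/JSON output
  (`runOverlapExperiment`, `runPccExperiment`, `runIntronExperiment`),
  and a thin CLI (`inst/scripts/loopsplice`) with subcommands
  `simulate-stack`, `simulate-beads`, `simulate-reads`, `register`,
  `segment`, `overlap`, `pcc`, `introns`, `stats`, `pipeline`.

Images travel as multi-page float TIFF with a JSON sidecar; annotations as
GFF3 or BED12 (converted to gene-local, 0-based half-open coordinates at
the boundary, minus-strand genes reflected); reads as BED12.

## Worked example

Simulate 25 nuclei in which every intron shorter than 10 kb persists 40 kb
downstream of its 3' end, probe the 1.9-kb intron 22 against a 153-kb
whole-gene clone, register, segment, and summarize:

```r
library(loopSplice)
res <- runOverlapExperiment(list(seed = 1, simulation = list(
  nNuclei = 25, delayKb = 40, intron = 22)))
res$log
#> [1] "24/25 nuclei passed QC"
head(res$table[, c("vIntron", "vBac", "vOverlap", "ratio", "containment")], 3)
#>   vIntron vBac vOverlap     ratio containment
#> 1     261 1448      261 0.1527209           1
#> 2     596 2698      596 0.1809466           1
#> 3     638 3071      638 0.1720280           1
res$summary$median
#> [1] 0.1711387
```

The median measured ratio, 0.171, is far above the no-delay expectation for
a 1.9-kb intron, `expectedOverlap(1.9, 153)` = 0.0124: the hallmark of
delayed splicing. Rerunning with `delayKb = 0` gives a median ratio of
about 0.05, a more than three-fold drop. One nucleus failed the 80%
containment QC (both alleles in a low-activity burst state) and is
excluded from the summary but retained in the table.

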