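# qualmer

Quality-weighted alignment-free comparison and clustering of sequencing
reads.

## The problem

Grouping NGS reads that originate from the same gene or genome — before
assembly, error correction or metagenomic binning — is usually done
alignment-free, by comparing k-mer count vectors with statistics such as

- **D2** = Σ<sub>w</sub> X<sub>w</sub> Y<sub>w</sub>, the inner product of
  the word-count vectors;
- **D2\*** = Σ<sub>w</sub> X̃<sub>w</sub> Ỹ<sub>w</sub> / (n−k+1)p<sub>w</sub>,
  with centred counts X̃<sub>w</sub> = X<sub>w</sub> − (n−k+1)p<sub>w</sub>
  under an i.i.d. background;
- **D2s** = Σ<sub>w</sub> X̃<sub>w</sub> Ỹ<sub>w</sub> /
  √(X̃<sub>w</sub>² + Ỹ<sub>w</sub>²);

plus L2, Kullback–Leibler and symmetrized KL on the word frequencies.

These statistics treat every k-mer occurrence as equally trustworthy, but a
sequencer also reports, for every base, a phred score
Q = −10·log₁₀ P(error). `qualmer` implements quality-weighted versions in
which each occurrence of a word contributes its probability of having been
read correctly, P<sub>w,i</sub> = Π<sub>j</sub> (1 − 10^(−Q(i+j)/10)):

- **D2<sup>q</sup>**, **D2\*<sup>q</sup>**, **D2<sup>sq</sup>** replace
  X<sub>w</sub> by X<sub>w</sub><sup>q</sup> = Σ occurrences P<sub>w,i</sub>,
  with the expected-count term (n−k+1)p<sub>w</sub>E(P<sub>w</sub>);
- **E(P<sub>w</sub>)** is estimated dataset-wide either as the *average
  word probability* (AWP), Σ X<sub>w</sub><sup>q</sup> / Σ X<sub>w</sub>,
  or the *average quality probability* (AQP), the product over word
  positions of the mean phred converted back to a probability;
- optional **quality redistribution** credits the missing mass (1 − p) of
  each uncertain base to the three single-substitution neighbour words,
  proportionally to base frequencies in the read.

On top of the measures the package provides k-means clustering of reads
(multi-restart, no-improvement stopping rule), recall-rate evaluation
against known read origins, a quality-consistent read simulator, and a
small command line (`inst/exec/qualmer`).

## Worked example

Simulate three transcript-like references, sequence 200 reads of length
200 from each with 5% quality-consistent mismatches, cluster with the
quality-weighted centred statistic, and score against the ground truth:

```r
library(qualmer)

refs <- simulate_references(3, c(1000, 3000), seed = 7)
sim  <- simulate_reads(refs, reads_per_ref = 200, read_length = 200,
                       mismatch_rate = 0.05, seed = 8)

cl <- cluster_reads(sim$reads, k = 3, centers = 3,
                    measure = "d2star_q", estimator = "aqp", seed = 9)
cl
#> <read_clustering> 600 reads into 3 clusters
#>   measure: d2star_q (AQP)
#>   distortion 303.425 (best of 5 runs, run 1, 16 iterations)

recall_by_source(cl, sim$truth)
#> # A tibble: 3 x 4
#>   source cluster n_reads recall
#>   <chr>    <int>   <int>  <dbl>
#> 1 ref01        2     200  0.865
#> 2 ref02        3     200  0.87
#> 3 ref03        1     200  0.81

recall_rate(cl, sim$truth)
#> [1] 0.8483333
```

The distortion is the summed dissimilarity of reads to their assigned
centroids (lower is better within one measure); the recall of a source is
the fraction of its reads captured by the cluster holding their plurality,
and the mean recall weights sources equally. Under the same seed the
classical `measure = "d2star"` reaches 0.827 here — the quality weighting
recovers part of what the injected errors destroy. `tidy(cl)` returns the
per-read assignments, `glance(cl)` the run summary, and `autoplot(cl)` a
PCA view of the profiles coloured by cluster.

The same pipeline is available from the shell:

```sh
qualmer simulate --refs 3 --reads-per-ref 200 --mismatch 0.05 --seed 7 --out sim
qualmer cluster sim.fastq -k 3 -c 3 --measure d2star-q --estimator aqp --seed 9 --out run
qualmer evaluate run_assignments.tsv --truth sim_truth.tsv
```

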