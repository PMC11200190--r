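# dtifuse

Multimodal drug–target interaction (DTI) prediction in R.

`dtifuse` predicts whether a small molecule interacts with a protein from four
views of the pair:

1. the drug's **SMILES string** (character tokens),
2. the drug's **molecular graph** (atoms and bonds),
3. the protein **amino-acid sequence** (residue tokens),
4. the protein **k-mer sequence** (overlapping length-k windows, default k = 2).

Token streams are embedded and encoded with convolutional blocks; the
molecular graph is encoded with a **readout-free directed message-passing
neural network (D-MPNN)**, whose hidden states live on directed bonds and
whose messages exclude the reverse edge:

    h⁰_vw = ReLU(W_b [x_v ; e_vw])
    m^{t+1}_vw = Σ_{k ∈ N(v)\{w}} M(x_v, x_k, h^t_kv)
    h^{t+1}_vw = ReLU(W_f [h^t_vw ; m^{t+1}_vw])
    h_v = ReLU(W_α [x_v ; Σ_{k∈N(v)} h^T_kv])

No pooling (readout) is applied to the graph: each atom stays a token, so all
four modalities enter fusion as L × d feature matrices.

Fusion is a **two-level hierarchical multimodal self-attention (HMSA)**.
Level 1 stacks the two drug streams (and, separately, the two protein
streams) into one token stream and applies masked scaled-dot-product
self-attention, so the attention matrix realizes all four intra-/inter-modal
blocks at once:

    A = softmax( [Q_a;Q_b] [K_a;K_b]ᵀ / √d_k ),   H = A [V_a;V_b]

Level 2 repeats this on the concatenated drug and protein outputs. The fused
matrix splits back into four per-modality parts D_*, each is added to its
encoder input (residual), max-pooled over real positions into Z_*, and a
four-layer classifier (dropout + LeakyReLU after layers 1–3, sigmoid on the
final logit) maps [Z_smiles; Z_graph; Z_seq; Z_mer] to an interaction
probability trained with binary cross-entropy. This differs from
cross-attention fusion, whose output is, by construction, a convex
combination of the *value* modality's rows only — a limitation the package
demonstrates numerically in its test suite.

Because public DTI benchmarks require large downloads and GPU-scale training,
the package ships a **seeded synthetic benchmark generator** with a planted,
learnable rule: a pair interacts iff the molecule contains a pyridine-type
aromatic-nitrogen ring (visible in SMILES tokens *and* in the graph) and the
protein contains a fixed tetrapeptide motif (visible in the residue *and*
k-mer streams). A non-neural rule-matching oracle certifies every emitted
dataset is perfectly separable, so end-to-end learnability is testable
offline in minutes.

All neural components — embeddings, 1-D convolutions, the D-MPNN, attention,
the classifier, reverse-mode gradients and the Adam optimizer — are
implemented in R on base matrix operations. SMILES parsing uses
ChemmineR/OpenBabel; AUC uses pROC.

## Worked example

```r
library(dtifuse)

# 500 drug-protein pairs with the planted rule (balanced labels), seed 7
ds  <- gen_dti_dataset(synth_config(n_pairs = 500, seed = 7))
rec <- ds$records

# desk-scale model: d = 32, T = 2, k = 2, 15 epochs, Adam 1e-3
cfg <- dti_desk_config(seed = 7)
ck  <- dti_train(cfg, rec, split = list(train = 1:360, validation = 361:400),
                 verbose = TRUE)
#> epoch   1  loss 0.6752  val AUC 0.9449
#> epoch   4  loss 0.2847  val AUC 1.0000
#> ...
#> epoch  15  loss 0.0007  val AUC 1.0000

evaluate(predict_pairs(ck$model, rec[401:500, ]))
#> AUC 0.9928 | AUPR 0.9929 | ACC 0.8100 | P 0.7286 | R 1.0000 (n=100, thr=0.50)
```

The held-out AUC/AUPR near 1 say the model recovered the planted
fragment-AND-motif rule from raw strings and graphs; the accuracy at the 0.5
threshold is lower because the balanced training split makes the classifier
confident on positives (recall 1.0) at the cost of precision. Candidate
ranking for a single drug works the same way:

```r
rank_candidates(ck$model, anchor = list(smiles = "c1ccncc1CCO"),
                candidates = gen_proteins(100, seed = 1), top_n = 20)
```

A thin CLI wraps the same functions (`simulate`, `train`, `evaluate`,
`predict`, `rank`, `ablate`):

```sh
Rscript inst/cli/dtifuse.R simulate --n-pairs 500 --seed 7 --out run1
Rscript inst/cli/dtifuse.R train --data run1/interactions.tsv --out run1
```

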