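# regcn

Unsupervised community (module) detection in undirected networks, with or
without node attributes — e.g. functional modules in protein-interaction
networks, conferences in social networks, or topical clusters in citation
graphs. The package turns community detection into a self-supervised node
classification problem: it finds one representative "structure center" per
community, manufactures pseudo-labels around those centers, and trains a
graph convolutional network (GCN) to label every node.

## Method

Given a graph with adjacency **A**, optional attribute matrix **X** (one-hot
node indicators when absent), and a community count *K*:

1. **Seeding (density peaks).** For each node, the local density
   ρ<sub>i</sub> = |{j ≠ i : d<sub>ij</sub> ≤ d<sub>c</sub>}| (hop distance,
   d<sub>c</sub> = 1 makes ρ the degree) and relative distance
   δ<sub>i</sub> = min{d<sub>ij</sub> : ρ<sub>j</sub> > ρ<sub>i</sub>} are
   combined into the structural centrality φ<sub>i</sub> = ρ<sub>i</sub>·δ<sub>i</sub>.
   The *K* largest-φ nodes become the initial structure centers.
2. **Refinement.** Repeat until the centers stop moving: train a fresh
   two-layer GCN, Z = softmax(Â ReLU(Â X W⁽⁰⁾) W⁽¹⁾) with
   Â = D̃<sup>-1/2</sup>(A+I)D̃<sup>-1/2</sup>, supervised only by the K
   centers; partition nodes by argmax<sub>k</sub> z<sub>i,k</sub>; inside
   each community's induced subgraph move the center to the node with the
   largest local structural importance w(v) = Σ<sub>j</sub> SLP(v, v<sub>j</sub>),
   where SLP is the α-weighted count of simple paths of lengths 1–3
   (α = 0.6, 0.35, 0.05).
3. **Expansion.** Around each refined center, collect the τ nodes of its
   predicted community whose affiliation strength is closest to the
   center's (|z<sub>x,k</sub> − z<sub>c_k,k</sub>| smallest). The bound
   K·τ·d̄<sup>L</sup> ≈ N (L = 2 layers, d̄ = mean degree) sets the default τ.
4. **Final model.** Train a fresh GCN on the expanded pseudo-labeled set by
   Adam on the summed cross-entropy −Σ<sub>k</sub>Σ<sub>i∈S_k</sub> log z<sub>i,k</sub>;
   the row-wise argmax of its output is the returned partition.

Agreement with ground truth is scored by best-mapping accuracy (optimal
label assignment), normalized mutual information, and adjusted Rand index.

## Worked example

```r
library(regcn)

# planted partition: 3 blocks of 50, within/between edge prob 0.25/0.02,
# 60 binary block-correlated attributes
g <- generateSBM(c(50, 50, 50), pIn = 0.25, pOut = 0.02, attrDim = 60, seed = 101)
g
#> CommunityGraph: 150 nodes, 1074 edges
#>   attributes: 60-dimensional
#>   ground truth: 3 communities

fit <- detectCommunities(g, k = 3, config = trainConfig(seed = 1))
fit
#> CommunityFit: 150 nodes partitioned into 3 communities
#>   community sizes: 50 50 50
#>   centers: 148 23 63
#>   pseudo-labels per community (tau): 1
#>   refinement: 2 iteration(s), stopped (stable)
#>   agreement with truth: ACC 100.00%  NMI 100.00%  ARI 100.00%
```

All three blocks are recovered exactly: the partition matches the planted
labels under the optimal label mapping (ACC), shares all its information
with them (NMI = 1), and agrees on every node pair (ARI = 1). The three
refined centers (nodes 148, 23, 63) are the block representatives; τ = 1
here because the graph is dense enough that two convolution layers already
reach every node from one seed per block.

The same pipeline is scriptable from a shell via `exec/regcn`:

```sh
regcn synth  --blocks 20,20 --pin 0.4 --pout 0.03 --attr-dim 16 --seed 3 --out demo
regcn detect --edges demo_edges.tsv --attrs demo_attrs.tsv --k 2 --seed 5 \
             --truth demo_labels.tsv --out demo_membership.tsv
regcn score  --truth demo_labels.tsv --pred demo_membership.tsv
# {"acc":100,"nmi":100,"ari":100}
```

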