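"""Batched 2-D UMAP embedding helper.

Reads a JSON payload {"n_neighbors": int, "min_dist": float, "seed": int,
"matrices": [[[row], ...], ...]} and writes a JSON list of 2-D coordinate
matrices. One process embeds many matrices so the numba JIT cost is paid
once per call. random_state is fixed, so results are deterministic.
"""
import json
import sys
import warnings

import numpy as np

warnings.filterwarnings("ignore")


def main(infile, outfile):
    with open(infile) as fh:
        payload = json.load(fh)
    import umap  # deferred: slow import

    out = []
    for mat in payload["matrices"]:
        x = np.asarray(mat, dtype=np.float64)
        n_neighbors = min(int(payload["n_neighbors"]), x.shape[0] - 1)
        reducer = umap.UMAP(
            n_components=2,
            n_neighbors=n_neighbors,
            min_dist=float(payload["min_dist"]),
            random_state=int(payload["seed"]),
            n_jobs=1,
        )
        out.append(reducer.fit_transform(x).tolist())
    with open(outfile, "w") as fh:
        json.dump(out, fh)


if __name__ == "__main__":
    main(sys.argv[1], sys.argv[2])
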