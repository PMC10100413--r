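"""Batched convex-hull volumes for the host R package.

Reads a JSON array of point sets (each a list of coordinate lists) from
argv[1], writes a JSON array of volumes (null for degenerate sets) to
argv[2].  Uses Qhull through scipy.spatial.ConvexHull.
"""
import json
import sys

import numpy as np
from scipy.spatial import ConvexHull, QhullError


def volume(points):
    pts = np.asarray(points, dtype=float)
    if pts.ndim != 2 or pts.shape[0] <= pts.shape[1]:
        return None
    try:
        return float(ConvexHull(pts).volume)
    except QhullError:
        return None


def main():
    with open(sys.argv[1]) as fh:
        sets = json.load(fh)
    out = [volume(p) for p in sets]
    with open(sys.argv[2], "w") as fh:
        json.dump(out, fh)


if __name__ == "__main__":
    main()
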