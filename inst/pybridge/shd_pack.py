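"""Pack a plain-text spike stream into an SHD-schema HDF5 file.

Usage: python shd_pack.py <in.txt> <out.h5>

Input format: as produced by shd_dump.py (times in seconds). Writes ragged
(variable-length) spikes/times and spikes/units datasets plus a labels
vector, mirroring the layout of the public SHD releases.
"""
import sys

import h5py
import numpy as np


def main(path, out):
    with open(path) as f:
        n = int(f.readline())
        labels = np.zeros(n, dtype=np.int64)
        times = []
        units = []
        for i in range(n):
            lab, k = f.readline().split()
            labels[i] = int(lab)
            k = int(k)
            tline = f.readline().split()
            uline = f.readline().split()
            if len(tline) != k or len(uline) != k:
                sys.stderr.write("LENGTH MISMATCH in sample %d\n" % i)
                return 2
            times.append(np.array([float(x) for x in tline]))
            units.append(np.array([int(x) for x in uline], dtype=np.int64))
    with h5py.File(out, "w") as h5:
        g = h5.create_group("spikes")
        dt = g.create_dataset("times", (n,), dtype=h5py.vlen_dtype(np.float64))
        du = g.create_dataset("units", (n,), dtype=h5py.vlen_dtype(np.int64))
        for i in range(n):
            dt[i] = times[i]
            du[i] = units[i]
        h5.create_dataset("labels", data=labels)
    return 0


if __name__ == "__main__":
    if len(sys.argv) != 3:
        sys.stderr.write("usage: shd_pack.py <in.txt> <out.h5>\n")
        sys.exit(2)
    sys.exit(main(sys.argv[1], sys.argv[2]))
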