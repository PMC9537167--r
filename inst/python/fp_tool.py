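"""Batch fingerprint/canonicalization helper around RDKit.

Called as a subprocess by the R package; one molecule per input line.
Modes:
  canon <infile>                       -> canonical SMILES or "" per line
  fp <infile> <family> <diameter> <nbits>
                                       -> space-separated set-bit indices
                                          (0-based) per line, "ERR" if the
                                          SMILES does not parse
  nenv <infile> <family> <diameter>    -> count of distinct unfolded
                                          environment identifiers per line
family: ECFP | FCFP; diameter: 0|2|4|6 (Morgan radius = diameter/2).
"""
import sys

from rdkit import Chem, RDLogger
from rdkit.Chem import rdFingerprintGenerator

RDLogger.DisableLog("rdApp.*")


def generator(family, diameter, nbits):
    kwargs = dict(radius=diameter // 2, fpSize=max(int(nbits), 1))
    if family == "FCFP":
        kwargs["atomInvariantsGenerator"] = (
            rdFingerprintGenerator.GetMorganFeatureAtomInvGen())
    elif family != "ECFP":
        raise SystemExit("unknown fingerprint family: %s" % family)
    return rdFingerprintGenerator.GetMorganGenerator(**kwargs)


def main(argv):
    mode, infile = argv[0], argv[1]
    with open(infile) as fh:
        smiles = [line.rstrip("\n") for line in fh]
    out = sys.stdout
    if mode == "canon":
        for smi in smiles:
            mol = Chem.MolFromSmiles(smi)
            out.write((Chem.MolToSmiles(mol) if mol is not None else "")
                      + "\n")
        return
    family, diameter = argv[2], int(argv[3])
    if mode == "fp":
        gen = generator(family, diameter, int(argv[4]))
        for smi in smiles:
            mol = Chem.MolFromSmiles(smi)
            if mol is None:
                out.write("ERR\n")
                continue
            bits = gen.GetFingerprint(mol).GetOnBits()
            out.write(" ".join(str(b) for b in bits) + "\n")
    elif mode == "nenv":
        gen = generator(family, diameter, 2048)
        for smi in smiles:
            mol = Chem.MolFromSmiles(smi)
            if mol is None:
                out.write("ERR\n")
                continue
            sfp = gen.GetSparseCountFingerprint(mol)
            out.write(str(len(sfp.GetNonzeroElements())) + "\n")
    else:
        raise SystemExit("unknown mode: %s" % mode)


if __name__ == "__main__":
    main(sys.argv[1:])
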