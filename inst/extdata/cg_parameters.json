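{
  "units": {
    "length": "nm",
    "energy": "kJ/mol",
    "angle": "rad",
    "charge": "e",
    "force_constant": "kJ nm-2 mol-1"
  },
  "er": 1,
  "cutoff": 1.2,
  "bonds": {
    "B-B": {
      "K": 100000,
      "L": 0.38
    },
    "B-S_ARG": {
      "K": 5000,
      "L": 0.406
    },
    "B-S_GLN": {
      "K": 5000,
      "L": 0.301
    },
    "B-S_GLU": {
      "K": 5000,
      "L": 0.295
    },
    "B-S_HIS": {
      "K": 5000,
      "L": 0.307
    },
    "B-S_ILE": {
      "K": 5000,
      "L": 0.226
    },
    "B-S_LYS": {
      "K": 5000,
      "L": 0.344
    },
    "B-S_MET": {
      "K": 5000,
      "L": 0.287
    },
    "B-S_PHE": {
      "K": 5000,
      "L": 0.333
    },
    "B-S_TRP": {
      "K": 5000,
      "L": 0.381
    },
    "B-S_TYR": {
      "K": 5000,
      "L": 0.371
    }
  },
  "angles": {
    "B-B-B": {
      "a": [44.9898622043087, 47.1460095253745, -18.9332590273686, 6.48099423762181, -12.4410945899286, 25.7071345653997],
      "b": [0.20546582020713, 2.94487098280223, 1.55171021353644, 2.25652268520911, 1.35187169829211, 1.46188884129154],
      "c": [1.28608514738522, 0.577577788379908, 0.203065042335989, 0.119135840298362, 0.0681159524705251, 0.621089479360111],
      "domain": "angle"
    },
    "B-B-S": {
      "a": [21.9558188848936, 9.73209723610172, 13.5300768529051, 27.6769827286137, -51, 14.1816642430874],
      "b": [0.851411212702179, 2.82475265296146, 1.58859221826384, 2.03842120662681, 2.05304124403794, 2.48190410806702],
      "c": [2.89181257364116, 0.867752296876143, 0.0810820993582841, 0.249657767388692, 0.394169243135007, 0.0640530300787523],
      "domain": "angle"
    }
  },
  "torsions": {
    "B-B-B-B": {
      "a": [6.31721889556362, 1.05714750244316, -6.46055605171806, -7.11267210358897],
      "b": [-1.43989658791649, 1.36286176322733, 3.10241894107633, 0.910268538735951],
      "c": [9.00761867299862, 0.944353227289211, 0.274267312651776, 0.286789746649029],
      "domain": "torsion"
    },
    "B-B-B-S": {
      "a": [0.365836414955303, 1.20090772900582, -7.57667790161022, -6.27089108551578],
      "b": [-2.13295736756798, 0.125927825151053, 0.0286829552862393, -1.37575623515878],
      "c": [0.650121918442426, 0.53588341229287, 0.304522722290192, 0.303176272014356],
      "domain": "torsion"
    },
    "S-B-B-S": {
      "a": [6.75812590843645, 5.87432852213552, -6.14611324232729, 3.7241776506309, -7.15249010491377, -7.19012373180046],
      "b": [1.89050767191005, 0.130899655175825, 1.0632190900771, 2.86109953665549, 3.09488536754802, 1.89675093379872],
      "c": [0.444728777124792, 3.48543750054573, 0.277659047727611, 1.55020346579567, 0.284691234024165, 0.602759355125755],
      "domain": "torsion"
    },
    "S-B-B-B": {
      "a": [1.58724790354918, 2.02207253802876, -6.62283053090594, 1.60569211193211, -6.2153463975685],
      "b": [-1.25689984727274, 2.05076184881436, -2.92501623821959, 0.34015832189268, -0.0837968067784858],
      "c": [1.48229529434, 2.57885682764981, 0.259466167540492, 0.110591324707016, 0.292785435456058],
      "domain": "torsion"
    }
  },
  "lj": [
    {
      "bead": "B_ALA",
      "eps": 3.20019398836969,
      "c": 0.5,
      "charge": 0
    },
    {
      "bead": "B_ASN",
      "eps": 3.40811724296887,
      "c": 0.6,
      "charge": 0
    },
    {
      "bead": "B_ASP",
      "eps": 2.99927494614549,
      "c": 0.55,
      "charge": -1
    },
    {
      "bead": "B_CYS",
      "eps": 3.79601148072972,
      "c": 0.5,
      "charge": 0
    },
    {
      "bead": "B_GLY",
      "eps": 2.79476040393804,
      "c": 0.4,
      "charge": 0
    },
    {
      "bead": "B_LEU",
      "eps": 4.39373343707928,
      "c": 0.55,
      "charge": 0
    },
    {
      "bead": "B_PRO",
      "eps": 3.60441995229952,
      "c": 0.65,
      "charge": 0
    },
    {
      "bead": "B_SER",
      "eps": 3.00403437038161,
      "c": 0.5,
      "charge": 0
    },
    {
      "bead": "B_THR",
      "eps": 3.19777292186676,
      "c": 0.5,
      "charge": 0
    },
    {
      "bead": "B_VAL",
      "eps": 4.00518281231936,
      "c": 0.5,
      "charge": 0
    },
    {
      "bead": "S_ARG",
      "eps": 3.01233715919629,
      "c": 0.6,
      "charge": 1
    },
    {
      "bead": "S_GLN",
      "eps": 3.18091096799169,
      "c": 0.45,
      "charge": 0
    },
    {
      "bead": "S_GLU",
      "eps": 2.99736264522895,
      "c": 0.45,
      "charge": -1
    },
    {
      "bead": "S_HIS",
      "eps": 3.49768954028484,
      "c": 0.45,
      "charge": 0
    },
    {
      "bead": "S_ILE",
      "eps": 4.49848428943186,
      "c": 0.5,
      "charge": 0
    },
    {
      "bead": "S_LYS",
      "eps": 2.99804786236063,
      "c": 0.45,
      "charge": 1
    },
    {
      "bead": "S_MET",
      "eps": 4.19500618696295,
      "c": 0.45,
      "charge": 0
    },
    {
      "bead": "S_PHE",
      "eps": 4.78530393511419,
      "c": 0.45,
      "charge": 0
    },
    {
      "bead": "S_TRP",
      "eps": 4.99433801598095,
      "c": 0.65,
      "charge": 0
    },
    {
      "bead": "S_TYR",
      "eps": 4.19564876515726,
      "c": 0.55,
      "charge": 0
    },
    {
      "bead": "W",
      "eps": 6,
      "c": 0.51,
      "charge": 0
    }
  ]
}
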