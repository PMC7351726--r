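{
  "name": "indirubin_3p_oxime",
  "atoms": [
    {
      "element": "N",
      "aromatic": true,
      "charge": 0,
      "nH": 1,
      "in_ring": true
    },
    {
      "element": "C",
      "aromatic": true,
      "charge": 0,
      "nH": 0,
      "in_ring": true
    },
    {
      "element": "C",
      "aromatic": true,
      "charge": 0,
      "nH": 0,
      "in_ring": true
    },
    {
      "element": "C",
      "aromatic": true,
      "charge": 0,
      "nH": 0,
      "in_ring": true
    },
    {
      "element": "C",
      "aromatic": true,
      "charge": 0,
      "nH": 1,
      "in_ring": true
    },
    {
      "element": "C",
      "aromatic": true,
      "charge": 0,
      "nH": 1,
      "in_ring": true
    },
    {
      "element": "C",
      "aromatic": true,
      "charge": 0,
      "nH": 1,
      "in_ring": true
    },
    {
      "element": "C",
      "aromatic": true,
      "charge": 0,
      "nH": 1,
      "in_ring": true
    },
    {
      "element": "C",
      "aromatic": true,
      "charge": 0,
      "nH": 0,
      "in_ring": true
    },
    {
      "element": "N",
      "aromatic": false,
      "charge": 0,
      "nH": 0,
      "in_ring": false
    },
    {
      "element": "N",
      "aromatic": true,
      "charge": 0,
      "nH": 1,
      "in_ring": true
    },
    {
      "element": "C",
      "aromatic": true,
      "charge": 0,
      "nH": 0,
      "in_ring": true
    },
    {
      "element": "C",
      "aromatic": true,
      "charge": 0,
      "nH": 0,
      "in_ring": true
    },
    {
      "element": "C",
      "aromatic": true,
      "charge": 0,
      "nH": 0,
      "in_ring": true
    },
    {
      "element": "C",
      "aromatic": true,
      "charge": 0,
      "nH": 1,
      "in_ring": true
    },
    {
      "element": "C",
      "aromatic": true,
      "charge": 0,
      "nH": 1,
      "in_ring": true
    },
    {
      "element": "C",
      "aromatic": true,
      "charge": 0,
      "nH": 1,
      "in_ring": true
    },
    {
      "element": "C",
      "aromatic": true,
      "charge": 0,
      "nH": 1,
      "in_ring": true
    },
    {
      "element": "C",
      "aromatic": true,
      "charge": 0,
      "nH": 0,
      "in_ring": true
    },
    {
      "element": "O",
      "aromatic": false,
      "charge": 0,
      "nH": 0,
      "in_ring": false
    },
    {
      "element": "O",
      "aromatic": false,
      "charge": 0,
      "nH": 1,
      "in_ring": false
    }
  ],
  "bonds": [
    {
      "a": 1,
      "b": 2,
      "order": "ar"
    },
    {
      "a": 2,
      "b": 3,
      "order": "ar"
    },
    {
      "a": 3,
      "b": 4,
      "order": "ar"
    },
    {
      "a": 4,
      "b": 9,
      "order": "ar"
    },
    {
      "a": 9,
      "b": 1,
      "order": "ar"
    },
    {
      "a": 4,
      "b": 5,
      "order": "ar"
    },
    {
      "a": 5,
      "b": 6,
      "order": "ar"
    },
    {
      "a": 6,
      "b": 7,
      "order": "ar"
    },
    {
      "a": 7,
      "b": 8,
      "order": "ar"
    },
    {
      "a": 8,
      "b": 9,
      "order": "ar"
    },
    {
      "a": 3,
      "b": 10,
      "order": "2"
    },
    {
      "a": 11,
      "b": 12,
      "order": "ar"
    },
    {
      "a": 12,
      "b": 13,
      "order": "ar"
    },
    {
      "a": 13,
      "b": 14,
      "order": "ar"
    },
    {
      "a": 14,
      "b": 19,
      "order": "ar"
    },
    {
      "a": 19,
      "b": 11,
      "order": "ar"
    },
    {
      "a": 14,
      "b": 15,
      "order": "ar"
    },
    {
      "a": 15,
      "b": 16,
      "order": "ar"
    },
    {
      "a": 16,
      "b": 17,
      "order": "ar"
    },
    {
      "a": 17,
      "b": 18,
      "order": "ar"
    },
    {
      "a": 18,
      "b": 19,
      "order": "ar"
    },
    {
      "a": 12,
      "b": 20,
      "order": "2"
    },
    {
      "a": 2,
      "b": 13,
      "order": "2"
    },
    {
      "a": 10,
      "b": 21,
      "order": "1"
    }
  ]
}
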