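## Idealized heavy-atom coordinates (Angstrom) for the 20 standard
## residues, taken from the PDB chemical component dictionary reference
## geometry. Backbone OXT and all hydrogens are omitted. Used by the
## synthetic structure generator to place rigid residues.
aa_atom_templates <- data.frame(
  resid = c("ALA", "ALA", "ALA", "ALA", "ALA", "ARG", "ARG", "ARG", "ARG", "ARG", "ARG", "ARG", "ARG", "ARG", "ARG", "ARG", "ASN", "ASN", "ASN", "ASN", "ASN", "ASN", "ASN", "ASN", "ASP", "ASP", "ASP", "ASP", "ASP", "ASP", "ASP", "ASP", "CYS", "CYS", "CYS", "CYS", "CYS", "CYS", "GLN", "GLN", "GLN", "GLN", "GLN", "GLN", "GLN", "GLN", "GLN", "GLU", "GLU", "GLU", "GLU", "GLU", "GLU", "GLU", "GLU", "GLU", "GLY", "GLY", "GLY", "GLY", "HIS", "HIS", "HIS", "HIS", "HIS", "HIS", "HIS", "HIS", "HIS", "HIS", "ILE", "ILE", "ILE", "ILE", "ILE", "ILE", "ILE", "ILE", "LEU", "LEU", "LEU", "LEU", "LEU", "LEU", "LEU", "LEU", "LYS", "LYS", "LYS", "LYS", "LYS", "LYS", "LYS", "LYS", "LYS", "MET", "MET", "MET", "MET", "MET", "MET", "MET", "MET", "PHE", "PHE", "PHE", "PHE", "PHE", "PHE", "PHE", "PHE", "PHE", "PHE", "PHE", "PRO", "PRO", "PRO", "PRO", "PRO", "PRO", "PRO", "SER", "SER", "SER", "SER", "SER", "SER", "THR", "THR", "THR", "THR", "THR", "THR", "THR", "TRP", "TRP", "TRP", "TRP", "TRP", "TRP", "TRP", "TRP", "TRP", "TRP", "TRP", "TRP", "TRP", "TRP", "TYR", "TYR", "TYR", "TYR", "TYR", "TYR", "TYR", "TYR", "TYR", "TYR", "TYR", "TYR", "VAL", "VAL", "VAL", "VAL", "VAL", "VAL", "VAL"),
  elety = c("N", "CA", "C", "O", "CB", "N", "CA", "C", "O", "CB", "CG", "CD", "NE", "CZ", "NH1", "NH2", "N", "CA", "C", "O", "CB", "CG", "OD1", "ND2", "N", "CA", "C", "O", "CB", "CG", "OD1", "OD2", "N", "CA", "C", "O", "CB", "SG", "N", "CA", "C", "O", "CB", "CG", "CD", "OE1", "NE2", "N", "CA", "C", "O", "CB", "CG", "CD", "OE1", "OE2", "N", "CA", "C", "O", "N", "CA", "C", "O", "CB", "CG", "ND1", "CD2", "CE1", "NE2", "N", "CA", "C", "O", "CB", "CG1", "CG2", "CD1", "N", "CA", "C", "O", "CB", "CG", "CD1", "CD2", "N", "CA", "C", "O", "CB", "CG", "CD", "CE", "NZ", "N", "CA", "C", "O", "CB", "CG", "SD", "CE", "N", "CA", "C", "O", "CB", "CG", "CD1", "CD2", "CE1", "CE2", "CZ", "N", "CA", "C", "O", "CB", "CG", "CD", "N", "CA", "C", "O", "CB", "OG", "N", "CA", "C", "O", "CB", "OG1", "CG2", "N", "CA", "C", "O", "CB", "CG", "CD1", "CD2", "NE1", "CE2", "CE3", "CZ2", "CZ3", "CH2", "N", "CA", "C", "O", "CB", "CG", "CD1", "CD2", "CE1", "CE2", "CZ", "OH", "N", "CA", "C", "O", "CB", "CG1", "CG2"),
  x = c(-0.966, 0.257, -0.094, -1.056, 1.204, -0.469, 0.004, -0.907, -1.827, 1.475, 1.745, 3.210, 4.071, 5.469, 6.259, 6.078, -0.293, -0.448, -1.846, -2.510, 0.562, 1.960, 2.132, 3.019, -0.317, -0.470, -1.868, -2.534, 0.539, 1.938, 2.109, 2.992, 1.585, 0.141, -0.095, 0.685, -0.533, -0.247, 1.858, 0.517, -0.236, -0.005, -0.236, 0.529, -0.213, -1.252, 0.277, 1.199, 1.138, 2.364, 3.010, -0.113, -1.360, -2.593, -2.485, -3.811, 1.931, 0.761, -0.498, -0.429, -0.040, 1.172, 1.083, 0.040, 1.484, 2.940, 3.380, 3.960, 4.693, 5.058, -1.944, -0.487, 0.066, -0.484, 0.140, -0.421, 1.658, 0.206, -1.661, -0.205, 0.180, -0.591, 0.221, -0.170, 0.256, 0.526, 1.422, 1.394, 2.657, 3.316, 0.184, -1.102, -2.313, -3.598, -4.761, -1.816, -0.392, 0.206, -0.236, 0.334, -0.273, 0.589, -0.314, 1.317, -0.020, -0.109, 0.879, -0.270, -0.181, 1.031, -1.314, 1.112, -1.231, -0.018, -0.816, 0.001, 1.408, 1.650, -0.703, -2.163, -2.218, 1.525, 0.100, -0.053, 0.751, -0.642, -0.496, 1.543, 0.122, -0.038, 0.732, -0.675, -0.193, -0.511, 1.278, -0.008, -0.490, 0.308, 0.168, 0.650, 1.928, -0.186, 1.978, 0.701, -1.564, 0.190, -2.044, -1.173, 1.320, -0.018, -0.103, 0.886, -0.274, -0.189, 1.022, -1.324, 1.103, -1.247, -0.032, 0.044, 1.564, 0.145, -0.037, 0.703, -0.682, -0.497, -0.218),
  y = c(0.493, 0.418, 0.017, -0.682, -0.620, 1.110, 2.294, 2.521, 1.789, 2.150, 1.017, 0.954, 0.726, 0.624, 0.404, 0.744, 1.686, 0.292, -0.179, 0.402, -0.588, -0.197, 0.697, -0.841, 1.688, 0.286, -0.180, 0.415, -0.580, -0.195, 0.681, -0.826, 0.483, 0.450, 0.006, -0.742, -0.530, 0.004, -0.148, 0.451, 0.022, -1.049, -0.013, 0.421, -0.036, -0.650, 0.236, 1.867, 0.515, -0.260, 0.096, -0.200, 0.517, -0.187, -1.161, 0.269, 0.090, -0.799, 0.029, 1.235, -1.210, -1.709, -3.207, -3.770, -0.975, -1.060, -2.075, -0.251, -1.908, -0.801, 0.335, 0.519, -0.032, -0.958, -0.219, 0.341, -0.027, -0.397, 0.627, 0.441, -0.055, -0.731, -0.583, -0.079, -1.104, 1.254, 1.796, 0.355, -0.284, 0.275, -0.278, 0.282, -0.351, 0.208, -0.400, 0.142, 0.499, 0.002, -0.989, -0.145, 0.359, -0.405, 0.353, 0.962, 0.426, 0.047, -0.317, -0.809, -0.430, -0.498, -0.018, -0.150, 0.333, 0.265, 1.108, -0.107, 0.091, 0.980, -1.227, -0.753, 0.614, 0.493, 0.469, 0.004, -0.760, -0.489, -0.049, -0.702, -0.706, -0.090, 0.761, 0.104, 1.448, -0.521, 1.121, 0.417, 0.076, -0.130, -0.868, -0.526, -0.418, -0.256, -0.095, 0.014, -0.210, 0.314, 0.086, 0.348, 0.952, 0.429, 0.094, -0.254, -0.831, -0.496, -0.589, -0.102, -0.282, 0.210, 0.118, 0.420, -0.642, -0.698, -0.093, 0.784, 0.086, -0.528, 1.543),
  z = c(1.500, 0.692, -0.716, -0.923, 1.296, -0.993, -1.708, -2.901, -3.242, -2.127, -3.130, -3.557, -2.421, -2.528, -1.405, -3.773, 0.094, -0.340, -0.031, 0.794, 0.401, -0.002, -0.804, 0.527, 0.066, -0.344, -0.029, 0.786, 0.413, 0.004, -0.810, 0.543, -0.081, 0.186, 1.606, 2.143, -0.774, -2.484, 1.125, 1.112, 2.344, 2.851, -0.135, -1.385, -2.614, -2.500, -3.839, -0.117, 0.453, 0.041, -0.916, -0.062, 0.461, -0.046, -0.753, 0.287, -0.034, -0.008, -0.005, -0.023, 0.053, 0.652, 0.905, 1.222, 1.962, 2.353, 3.129, 2.046, 3.317, 2.662, -0.343, -0.369, -1.657, -2.203, 0.814, 2.122, 0.788, 3.305, -0.406, -0.467, -1.836, -2.474, 0.585, 1.976, 3.029, 2.250, 0.198, 0.484, -0.032, -0.876, -0.206, 0.407, -0.283, 0.329, -0.332, -1.166, -1.214, -2.504, -3.033, -0.032, 1.277, 2.678, 4.056, 1.014, 1.300, 2.756, 3.346, 0.434, -1.020, -1.680, -1.698, -3.015, -3.032, -3.691, 0.254, 0.509, 0.005, -0.777, -0.286, -0.439, 0.276, -0.608, -0.252, 1.173, 1.649, -1.184, -2.535, 0.430, 0.056, -1.309, -1.683, 1.079, 1.103, 2.466, 2.059, 1.970, 3.357, 4.240, 1.161, -0.225, -0.622, -1.396, -1.951, -2.454, -1.615, -3.712, -2.859, -3.907, 1.428, 1.734, 3.201, 3.799, 0.907, -0.559, -1.219, -1.244, -2.563, -2.587, -3.252, -4.574, 0.454, 0.079, -1.288, -1.664, 1.098, 2.487, 1.119),
  stringsAsFactors = FALSE)
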