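f0_hz:
- '100.00000000000004'
- '118.92071150027211'
- '141.42135623730957'
- '168.17928305074292'
- '200.00000000000011'
- '237.84142300054424'
- '282.84271247461891'
- '336.35856610148585'
- '399.99999999999989'
- '100.00000000000004'
- '118.92071150027211'
- '141.42135623730957'
- '168.17928305074292'
- '200.00000000000011'
- '237.84142300054424'
- '282.84271247461891'
- '336.35856610148585'
- '399.99999999999989'
- '100.00000000000004'
- '118.92071150027211'
- '141.42135623730957'
- '168.17928305074292'
- '200.00000000000011'
- '237.84142300054424'
- '282.84271247461891'
- '336.35856610148585'
- '399.99999999999989'
- '100.00000000000004'
- '118.92071150027211'
- '141.42135623730957'
- '168.17928305074292'
- '200.00000000000011'
- '237.84142300054424'
- '282.84271247461891'
- '336.35856610148585'
- '399.99999999999989'
- '100.00000000000004'
- '118.92071150027211'
- '141.42135623730957'
- '168.17928305074292'
- '200.00000000000011'
- '237.84142300054424'
- '282.84271247461891'
- '336.35856610148585'
- '399.99999999999989'
- '100.00000000000004'
- '118.92071150027211'
- '141.42135623730957'
- '168.17928305074292'
- '200.00000000000011'
- '237.84142300054424'
- '282.84271247461891'
- '336.35856610148585'
- '399.99999999999989'
- '100.00000000000004'
- '118.92071150027211'
- '141.42135623730957'
- '168.17928305074292'
- '200.00000000000011'
- '237.84142300054424'
- '282.84271247461891'
- '336.35856610148585'
- '399.99999999999989'
- '100.00000000000004'
- '118.92071150027211'
- '141.42135623730957'
- '168.17928305074292'
- '200.00000000000011'
- '237.84142300054424'
- '282.84271247461891'
- '336.35856610148585'
- '399.99999999999989'
- '100.00000000000004'
- '118.92071150027211'
- '141.42135623730957'
- '168.17928305074292'
- '200.00000000000011'
- '237.84142300054424'
- '282.84271247461891'
- '336.35856610148585'
- '399.99999999999989'
- '100.00000000000004'
- '118.92071150027211'
- '141.42135623730957'
- '168.17928305074292'
- '200.00000000000011'
- '237.84142300054424'
- '282.84271247461891'
- '336.35856610148585'
- '399.99999999999989'
- '100.00000000000004'
- '118.92071150027211'
- '141.42135623730957'
- '168.17928305074292'
- '200.00000000000011'
- '237.84142300054424'
- '282.84271247461891'
- '336.35856610148585'
- '399.99999999999989'
- '100.00000000000004'
- '118.92071150027211'
- '141.42135623730957'
- '168.17928305074292'
- '200.00000000000011'
- '237.84142300054424'
- '282.84271247461891'
- '336.35856610148585'
- '399.99999999999989'
- '100.00000000000004'
- '118.92071150027211'
- '141.42135623730957'
- '168.17928305074292'
- '200.00000000000011'
- '237.84142300054424'
- '282.84271247461891'
- '336.35856610148585'
- '399.99999999999989'
- '100.00000000000004'
- '118.92071150027211'
- '141.42135623730957'
- '168.17928305074292'
- '200.00000000000011'
- '237.84142300054424'
- '282.84271247461891'
- '336.35856610148585'
- '399.99999999999989'
- '100.00000000000004'
- '118.92071150027211'
- '141.42135623730957'
- '168.17928305074292'
- '200.00000000000011'
- '237.84142300054424'
- '282.84271247461891'
- '336.35856610148585'
- '399.99999999999989'
- '100.00000000000004'
- '118.92071150027211'
- '141.42135623730957'
- '168.17928305074292'
- '200.00000000000011'
- '237.84142300054424'
- '282.84271247461891'
- '336.35856610148585'
- '399.99999999999989'
- '100.00000000000004'
- '118.92071150027211'
- '141.42135623730957'
- '168.17928305074292'
- '200.00000000000011'
- '237.84142300054424'
- '282.84271247461891'
- '336.35856610148585'
- '399.99999999999989'
- '100.00000000000004'
- '118.92071150027211'
- '141.42135623730957'
- '168.17928305074292'
- '200.00000000000011'
- '237.84142300054424'
- '282.84271247461891'
- '336.35856610148585'
- '399.99999999999989'
n_min:
- 2
- 2
- 2
- 2
- 2
- 2
- 2
- 2
- 2
- 2
- 2
- 2
- 2
- 2
- 2
- 2
- 2
- 2
- 2
- 2
- 2
- 2
- 2
- 2
- 2
- 2
- 2
- 3
- 3
- 3
- 3
- 3
- 3
- 3
- 3
- 3
- 3
- 3
- 3
- 3
- 3
- 3
- 3
- 3
- 3
- 3
- 3
- 3
- 3
- 3
- 3
- 3
- 3
- 3
- 4
- 4
- 4
- 4
- 4
- 4
- 4
- 4
- 4
- 4
- 4
- 4
- 4
- 4
- 4
- 4
- 4
- 4
- 4
- 4
- 4
- 4
- 4
- 4
- 4
- 4
- 4
- 5
- 5
- 5
- 5
- 5
- 5
- 5
- 5
- 5
- 5
- 5
- 5
- 5
- 5
- 5
- 5
- 5
- 5
- 5
- 5
- 5
- 5
- 5
- 5
- 5
- 5
- 5
- 6
- 6
- 6
- 6
- 6
- 6
- 6
- 6
- 6
- 6
- 6
- 6
- 6
- 6
- 6
- 6
- 6
- 6
- 6
- 6
- 6
- 6
- 6
- 6
- 6
- 6
- 6
- 7
- 7
- 7
- 7
- 7
- 7
- 7
- 7
- 7
- 7
- 7
- 7
- 7
- 7
- 7
- 7
- 7
- 7
- 7
- 7
- 7
- 7
- 7
- 7
- 7
- 7
- 7
n_harmonics:
- 2
- 2
- 2
- 2
- 2
- 2
- 2
- 2
- 2
- 3
- 3
- 3
- 3
- 3
- 3
- 3
- 3
- 3
- 4
- 4
- 4
- 4
- 4
- 4
- 4
- 4
- 4
- 2
- 2
- 2
- 2
- 2
- 2
- 2
- 2
- 2
- 3
- 3
- 3
- 3
- 3
- 3
- 3
- 3
- 3
- 4
- 4
- 4
- 4
- 4
- 4
- 4
- 4
- 4
- 2
- 2
- 2
- 2
- 2
- 2
- 2
- 2
- 2
- 3
- 3
- 3
- 3
- 3
- 3
- 3
- 3
- 3
- 4
- 4
- 4
- 4
- 4
- 4
- 4
- 4
- 4
- 2
- 2
- 2
- 2
- 2
- 2
- 2
- 2
- 2
- 3
- 3
- 3
- 3
- 3
- 3
- 3
- 3
- 3
- 4
- 4
- 4
- 4
- 4
- 4
- 4
- 4
- 4
- 2
- 2
- 2
- 2
- 2
- 2
- 2
- 2
- 2
- 3
- 3
- 3
- 3
- 3
- 3
- 3
- 3
- 3
- 4
- 4
- 4
- 4
- 4
- 4
- 4
- 4
- 4
- 2
- 2
- 2
- 2
- 2
- 2
- 2
- 2
- 2
- 3
- 3
- 3
- 3
- 3
- 3
- 3
- 3
- 3
- 4
- 4
- 4
- 4
- 4
- 4
- 4
- 4
- 4
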