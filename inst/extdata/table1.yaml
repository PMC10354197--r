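backrest_angle_deg: 24.0
segments:
- id: 1
  name: head
  mass_kg: 6.13
  partner: ~
- id: 2
  name: thorax
  mass_kg: 14.390000000000001
  partner: ~
- id: 3
  name: abdomen
  mass_kg: 10.18
  partner: ~
- id: 4
  name: pelvis
  mass_kg: 11.220000000000001
  partner: ~
- id: 5
  name: upper-arm-L
  mass_kg: 2.26
  partner: 8
- id: 6
  name: forearm-L
  mass_kg: 1.34
  partner: 9
- id: 7
  name: hand-L
  mass_kg: 0.77
  partner: 10
- id: 8
  name: upper-arm-R
  mass_kg: 2.26
  partner: 5
- id: 9
  name: forearm-R
  mass_kg: 1.34
  partner: 6
- id: 10
  name: hand-R
  mass_kg: 0.77
  partner: 7
- id: 11
  name: thigh-L
  mass_kg: 8.15
  partner: 14
- id: 12
  name: leg-L
  mass_kg: 3.14
  partner: 15
- id: 13
  name: foot-L
  mass_kg: 1.24
  partner: 16
- id: 14
  name: thigh-R
  mass_kg: 8.15
  partner: 11
- id: 15
  name: leg-R
  mass_kg: 3.14
  partner: 12
- id: 16
  name: foot-R
  mass_kg: 1.24
  partner: 13
connections:
- index: 1
  end_a: '2'
  end_b: 1
  joint: neck
  partner: ~
  k:
    xx: 162000.0
    xz: 74000.0
    zx: 74000.0
    zz: 239000.0
  c:
    xx: 1210.0
    xz: 450.0
    zx: 450.0
    zz: 2060.0
- index: 2
  end_a: '3'
  end_b: 2
  joint: thorax-abdomen
  partner: ~
  k:
    xx: 172000.0
    xz: 49000.0
    zx: 49000.0
    zz: 245000.000000000029104
  c:
    xx: 1240.0
    xz: 260.0
    zx: 260.0
    zz: 1860.0
- index: 3
  end_a: '4'
  end_b: 3
  joint: abdomen-pelvis
  partner: ~
  k:
    xx: 194000.0
    xz: 64000.0
    zx: 64000.0
    zz: 238000.0
  c:
    xx: 1060.0
    xz: 480.0
    zx: 480.0
    zz: 1260.0
- index: 4
  end_a: SEAT
  end_b: 4
  joint: seat-cushion
  partner: ~
  k:
    xx: 224000.000000000029104
    xz: 126000.0
    zx: 126000.0
    zz: 250999.999999999970896
  c:
    xx: 1440.0
    xz: 670.0
    zx: 670.0
    zz: 2190.0
- index: 5
  end_a: '2'
  end_b: 5
  joint: shoulder-L
  partner: 8
  k:
    xx: 134000.0
    xz: 61000.0
    zx: 61000.0
    zz: 167000.0
  c:
    xx: 1130.0
    xz: 720.0
    zx: 720.0
    zz: 1840.0
- index: 6
  end_a: '5'
  end_b: 6
  joint: elbow-L
  partner: 9
  k:
    xx: 167000.0
    xz: 35000.0
    zx: 35000.0
    zz: 206999.999999999970896
  c:
    xx: 1340.0
    xz: 570.0
    zx: 570.0
    zz: 1940.0
- index: 7
  end_a: '6'
  end_b: 7
  joint: wrist-L
  partner: 10
  k:
    xx: 117000.0
    xz: 54000.0
    zx: 54000.0
    zz: 185000.0
  c:
    xx: 1460.0
    xz: 610.0
    zx: 610.0
    zz: 2009.999999999999773
- index: 8
  end_a: '2'
  end_b: 8
  joint: shoulder-R
  partner: 5
  k:
    xx: 134000.0
    xz: 61000.0
    zx: 61000.0
    zz: 167000.0
  c:
    xx: 1130.0
    xz: 720.0
    zx: 720.0
    zz: 1840.0
- index: 9
  end_a: '8'
  end_b: 9
  joint: elbow-R
  partner: 6
  k:
    xx: 167000.0
    xz: 35000.0
    zx: 35000.0
    zz: 206999.999999999970896
  c:
    xx: 1340.0
    xz: 570.0
    zx: 570.0
    zz: 1940.0
- index: 10
  end_a: '9'
  end_b: 10
  joint: wrist-R
  partner: 7
  k:
    xx: 117000.0
    xz: 54000.0
    zx: 54000.0
    zz: 185000.0
  c:
    xx: 1460.0
    xz: 610.0
    zx: 610.0
    zz: 2009.999999999999773
- index: 11
  end_a: '4'
  end_b: 2
  joint: lumbar-support-upper
  partner: ~
  k:
    xx: 127000.0
    xz: 85000.0
    zx: 85000.0
    zz: 164000.0
  c:
    xx: 1890.0
    xz: 1170.0
    zx: 1170.0
    zz: 2280.0
- index: 12
  end_a: '4'
  end_b: 3
  joint: lumbar-support-lower
  partner: ~
  k:
    xx: 192000.0
    xz: 145000.0
    zx: 145000.0
    zz: 256000.0
  c:
    xx: 2260.0
    xz: 1540.0
    zx: 1540.0
    zz: 2610.0
- index: 13
  end_a: '4'
  end_b: 1
  joint: headrest-frame
  partner: ~
  k:
    xx: 172000.0
    xz: 46000.0
    zx: 46000.0
    zz: 219000.0
  c:
    xx: 1170.0
    xz: 840.0
    zx: 840.0
    zz: 2300.0
- index: 14
  end_a: '4'
  end_b: 11
  joint: hip-L
  partner: 15
  k:
    xx: 162000.0
    xz: 42000.0
    zx: 42000.0
    zz: 186000.0
  c:
    xx: 1240.0
    xz: 610.0
    zx: 610.0
    zz: 2130.0
- index: 15
  end_a: '4'
  end_b: 14
  joint: hip-R
  partner: 14
  k:
    xx: 172000.0
    xz: 46000.0
    zx: 46000.0
    zz: 219000.0
  c:
    xx: 1170.0
    xz: 840.0
    zx: 840.0
    zz: 2300.0
- index: 16
  end_a: '11'
  end_b: 12
  joint: knee-L
  partner: 17
  k:
    xx: 162000.0
    xz: 42000.0
    zx: 42000.0
    zz: 186000.0
  c:
    xx: 1240.0
    xz: 610.0
    zx: 610.0
    zz: 2130.0
- index: 17
  end_a: '14'
  end_b: 15
  joint: knee-R
  partner: 16
  k:
    xx: 176000.0
    xz: 34000.0
    zx: 34000.0
    zz: 237000.0
  c:
    xx: 1150.0
    xz: 650.0
    zx: 650.0
    zz: 2140.0
- index: 18
  end_a: '12'
  end_b: 13
  joint: ankle-L
  partner: 19
  k:
    xx: 126000.0
    xz: 64000.0
    zx: 64000.0
    zz: 184000.0
  c:
    xx: 1260.0
    xz: 510.0
    zx: 510.0
    zz: 1960.0
- index: 19
  end_a: '15'
  end_b: 16
  joint: ankle-R
  partner: 18
  k:
    xx: 109000.000000000014552
    xz: 71000.0
    zx: 71000.0
    zz: 176000.0
  c:
    xx: 1370.0
    xz: 650.0
    zx: 650.0
    zz: 2120.0
- index: 20
  end_a: '4'
  end_b: 11
  joint: seat-pan-thigh-L
  partner: 21
  k:
    xx: 112999.999999999985448
    xz: 32000.0
    zx: 32000.0
    zz: 175000.0
  c:
    xx: 720.0
    xz: 260.0
    zx: 260.0
    zz: 1510.0
- index: 21
  end_a: '4'
  end_b: 14
  joint: seat-pan-thigh-R
  partner: 20
  k:
    xx: 164000.0
    xz: 51000.0
    zx: 51000.0
    zz: 213000.0
  c:
    xx: 1150.0
    xz: 640.0
    zx: 640.0
    zz: 2140.0
- index: 22
  end_a: '4'
  end_b: 13
  joint: footrest-L
  partner: 23
  k:
    xx: 176000.0
    xz: 34000.0
    zx: 34000.0
    zz: 237000.0
  c:
    xx: 1150.0
    xz: 650.0
    zx: 650.0
    zz: 2140.0
- index: 23
  end_a: '4'
  end_b: 16
  joint: footrest-R
  partner: 22
  k:
    xx: 126000.0
    xz: 64000.0
    zx: 64000.0
    zz: 184000.0
  c:
    xx: 1260.0
    xz: 510.0
    zx: 510.0
    zz: 1960.0
- index: 24
  end_a: '7'
  end_b: 11
  joint: hand-on-thigh-L
  partner: 25
  k:
    xx: 109000.000000000014552
    xz: 71000.0
    zx: 71000.0
    zz: 176000.0
  c:
    xx: 1370.0
    xz: 650.0
    zx: 650.0
    zz: 2120.0
- index: 25
  end_a: '10'
  end_b: 14
  joint: hand-on-thigh-R
  partner: 24
  k:
    xx: 112999.999999999985448
    xz: 32000.0
    zx: 32000.0
    zz: 175000.0
  c:
    xx: 720.0
    xz: 260.0
    zx: 260.0
    zz: 1510.0
- index: 26
  end_a: '4'
  end_b: 2
  joint: backrest-thorax
  partner: ~
  k:
    xx: 164000.0
    xz: 51000.0
    zx: 51000.0
    zz: 213000.0
  c:
    xx: 1150.0
    xz: 640.0
    zx: 640.0
    zz: 2140.0
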