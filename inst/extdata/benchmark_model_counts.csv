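complex,setting,total,constrained,unconstrained
1gla,unbound,500,0,0
1y64,unbound,500,0,0
1akj,unbound,500,10,3
1s1q,unbound,500,0,0
3bp8,unbound,500,4,0
1pvh,unbound,500,0,0
2nz8,unbound,500,1,1
2j0t,unbound,500,2,2
7cei,unbound,500,0,1
1ijk,unbound,500,0,0
2o3b,unbound,500,0,0
1jwh,unbound,500,0,0
1i2m,unbound,500,0,0
2pcc,unbound,500,2,0
1h1v,unbound,500,0,0
1b6c,unbound,500,0,0
2hle,unbound,500,1,0
1bkd,unbound,500,0,0
1he1,unbound,500,11,6
1m10,unbound,500,16,5
1i4d,unbound,500,0,0
1azs,unbound,500,0,0
2sni,unbound,500,1,1
1gpw,unbound,500,0,1
1ofu,unbound,500,3,0
1z0k,unbound,500,1,1
1jzd,unbound,500,0,0
1fak,unbound,500,0,0
1gla,unbound,1000,0,0
1y64,unbound,1000,0,0
1akj,unbound,1000,13,5
1s1q,unbound,1000,0,0
3bp8,unbound,1000,5,2
1pvh,unbound,1000,0,0
2nz8,unbound,1000,1,1
2j0t,unbound,1000,3,2
7cei,unbound,1000,0,1
1ijk,unbound,1000,0,0
2o3b,unbound,1000,0,0
1jwh,unbound,1000,1,0
1i2m,unbound,1000,0,0
2pcc,unbound,1000,3,0
1h1v,unbound,1000,0,0
1b6c,unbound,1000,1,1
2hle,unbound,1000,2,1
1bkd,unbound,1000,0,0
1he1,unbound,1000,18,12
1m10,unbound,1000,19,5
1i4d,unbound,1000,0,0
1azs,unbound,1000,0,0
2sni,unbound,1000,1,2
1gpw,unbound,1000,2,1
1ofu,unbound,1000,4,0
1z0k,unbound,1000,3,1
1jzd,unbound,1000,0,0
1fak,unbound,1000,0,0
1gla,unbound,2000,0,0
1y64,unbound,2000,0,0
1akj,unbound,2000,15,6
1s1q,unbound,2000,0,0
3bp8,unbound,2000,9,4
1pvh,unbound,2000,0,0
2nz8,unbound,2000,3,2
2j0t,unbound,2000,7,3
7cei,unbound,2000,0,1
1ijk,unbound,2000,0,0
2o3b,unbound,2000,0,0
1jwh,unbound,2000,5,0
1i2m,unbound,2000,0,0
2pcc,unbound,2000,4,1
1h1v,unbound,2000,0,0
1b6c,unbound,2000,2,1
2hle,unbound,2000,3,1
1bkd,unbound,2000,0,0
1he1,unbound,2000,30,17
1m10,unbound,2000,27,11
1i4d,unbound,2000,0,0
1azs,unbound,2000,0,0
2sni,unbound,2000,1,3
1gpw,unbound,2000,2,3
1ofu,unbound,2000,6,1
1z0k,unbound,2000,16,4
1jzd,unbound,2000,1,0
1fak,unbound,2000,0,0
1gla,unbound,5000,0,0
1y64,unbound,5000,0,0
1akj,unbound,5000,26,13
1s1q,unbound,5000,0,0
3bp8,unbound,5000,27,14
1pvh,unbound,5000,0,0
2nz8,unbound,5000,4,3
2j0t,unbound,5000,11,7
7cei,unbound,5000,0,4
1ijk,unbound,5000,1,1
2o3b,unbound,5000,10,4
1jwh,unbound,5000,9,1
1i2m,unbound,5000,3,0
2pcc,unbound,5000,8,1
1h1v,unbound,5000,0,0
1b6c,unbound,5000,2,1
2hle,unbound,5000,11,3
1bkd,unbound,5000,0,0
1he1,unbound,5000,53,34
1m10,unbound,5000,54,17
1i4d,unbound,5000,0,0
1azs,unbound,5000,0,0
2sni,unbound,5000,3,16
1gpw,unbound,5000,13,10
1ofu,unbound,5000,10,1
1z0k,unbound,5000,39,20
1jzd,unbound,5000,2,4
1fak,unbound,5000,0,0
1gla,bound,500,1,1
1y64,bound,500,0,1
1akj,bound,500,5,5
1s1q,bound,500,4,12
3bp8,bound,500,9,8
1pvh,bound,500,2,1
2nz8,bound,500,23,9
2j0t,bound,500,10,5
7cei,bound,500,5,1
1ijk,bound,500,2,2
2o3b,bound,500,0,0
1jwh,bound,500,0,0
1i2m,bound,500,1,1
2pcc,bound,500,2,0
1h1v,bound,500,2,2
1b6c,bound,500,21,25
2hle,bound,500,2,0
1bkd,bound,500,19,6
1he1,bound,500,32,3
1m10,bound,500,36,9
1i4d,bound,500,4,7
1azs,bound,500,16,2
2sni,bound,500,26,14
1gpw,bound,500,25,14
1ofu,bound,500,7,0
1z0k,bound,500,36,17
1jzd,bound,500,29,7
1fak,bound,500,1,1
1gla,bound,1000,2,2
1y64,bound,1000,0,2
1akj,bound,1000,8,8
1s1q,bound,1000,5,16
3bp8,bound,1000,10,13
1pvh,bound,1000,2,1
2nz8,bound,1000,38,10
2j0t,bound,1000,12,5
7cei,bound,1000,6,1
1ijk,bound,1000,2,2
2o3b,bound,1000,0,0
1jwh,bound,1000,0,0
1i2m,bound,1000,3,1
2pcc,bound,1000,5,5
1h1v,bound,1000,3,3
1b6c,bound,1000,36,35
2hle,bound,1000,4,0
1bkd,bound,1000,35,9
1he1,bound,1000,42,5
1m10,bound,1000,54,14
1i4d,bound,1000,5,8
1azs,bound,1000,24,2
2sni,bound,1000,41,26
1gpw,bound,1000,42,22
1ofu,bound,1000,18,0
1z0k,bound,1000,58,27
1jzd,bound,1000,44,13
1fak,bound,1000,1,2
1gla,bound,2000,2,4
1y64,bound,2000,0,2
1akj,bound,2000,14,12
1s1q,bound,2000,6,30
3bp8,bound,2000,12,25
1pvh,bound,2000,3,2
2nz8,bound,2000,50,12
2j0t,bound,2000,20,8
7cei,bound,2000,7,1
1ijk,bound,2000,3,3
2o3b,bound,2000,0,0
1jwh,bound,2000,0,0
1i2m,bound,2000,6,3
2pcc,bound,2000,8,6
1h1v,bound,2000,5,6
1b6c,bound,2000,62,43
2hle,bound,2000,9,2
1bkd,bound,2000,67,15
1he1,bound,2000,77,9
1m10,bound,2000,75,17
1i4d,bound,2000,9,11
1azs,bound,2000,48,3
2sni,bound,2000,70,38
1gpw,bound,2000,73,26
1ofu,bound,2000,38,2
1z0k,bound,2000,92,43
1jzd,bound,2000,67,14
1fak,bound,2000,6,4
1gla,bound,5000,7,8
1y64,bound,5000,0,3
1akj,bound,5000,18,21
1s1q,bound,5000,8,41
3bp8,bound,5000,18,42
1pvh,bound,5000,5,3
2nz8,bound,5000,70,23
2j0t,bound,5000,30,20
7cei,bound,5000,7,1
1ijk,bound,5000,5,5
2o3b,bound,5000,1,1
1jwh,bound,5000,3,0
1i2m,bound,5000,12,6
2pcc,bound,5000,15,13
1h1v,bound,5000,10,8
1b6c,bound,5000,117,61
2hle,bound,5000,16,5
1bkd,bound,5000,106,20
1he1,bound,5000,140,17
1m10,bound,5000,106,22
1i4d,bound,5000,13,22
1azs,bound,5000,58,7
2sni,bound,5000,142,82
1gpw,bound,5000,132,41
1ofu,bound,5000,75,4
1z0k,bound,5000,179,85
1jzd,bound,5000,110,27
1fak,bound,5000,11,6
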