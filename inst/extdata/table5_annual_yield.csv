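genotype,marker,mws_tdw,mws_cpy,sws_tdw,sws_cpy
1026,,18.9p,1281.06l,17.99b,1448.47hi
14355,**,48.48ij,3240.65ghij,48.21fg,3648.34efg
14389,,29.28cdefg,2154.83wxy,27.75uv,2172.14uvwxy
14982,,31.91yzab,2375.85stu,30.83rst,2343.17stu
14983,,43.95k,3423.47ef,43.31h,3862.63de
14984,,41.02lmno,2663.53p,39.33jk,2877.39lm
15357,**,49.97hi,3342.45efgh,47.66fg,3572.8fg
16621,,2.9t,164.84p,2.66f,201.87lm
16782,,31.53yzabc,2139.68wxyz,31.71pqrs,2080.56vwxyza
16783,,40.43mno,2511.52qrs,38.16kl,2647.38nopqr
16784,,32.75xyza,2369.07tu,32.33pqr,2691.07nopq
16785,,27.76efghi,1515.86ijk,27.47vw,1808.73bcdef
16786,,33.3wxyz,2025.89yzab,31.6rs,2260.51tuvw
16787,,23.34klmn,1522.19ij,21.21za,1668.73fgh
16788,,29.66bcdef,1978.48zab,27.61uv,2080.21vwxyza
16789,,38.09pqrs,2313.41uv,36.9lmn,2619.82opqr
16790,,11.64r,813.97n,10.45d,790.64k
16791,**,68.05a,4429.1a,67.35a,5213.84a
16792,,39.54op,2200.51vwx,38.41kl,2494.38rs
16793,,25.56ijk,1585.26ghi,23.86xy,1669.11fgh
16794,,33.46wxy,2333.49tuv,31.63qrs,2705.3mnopq
16795,,42klmn,2632.63pq,40.48ij,2828.19lmn
16796,,21.16nop,1393.36jkl,19.71ab,1534.64ghi
16797,,6.28s,464.86o,6.11e,421.85l
16798,,31.89yzab,1966.69abc,31.62qrs,2247.3tuvw
16799,,25.1jkl,1693.38fgh,23.87xy,1737.6defg
16800,,33.72vwxy,2024.91yzab,31.95pqrs,2180.03uvwxy
16801,,30.26bcd,1829.93cdef,28.89tuv,1987.33xyzabc
16802,**,55.11de,3342.67efgh,55.47d,3966.85cd
16803,,30.69abcd,2028.23yzab,27.25vw,1918.03zabcde
16804,,30.09bcdef,2202.14vwx,27.73uv,2219.09uvwx
16805,,5.1s,400.24o,4.79e,297.49lm
16806,,30.59bcd,2017.28yzab,28.36uv,1957.29yzabcd
16807,,43kl,3297.35fghi,42.26hi,3201.01ijk
16808,,29.74bcdef,2008.26yzab,28.74tuv,2152.11uvwxyz
16809,,33.84vwxy,2370.2stu,30.95rst,2113.2uvwxyz
16810,,21.61no,1582.54ghi,21.09za,1494.81hi
16811,*,41.69klmn,3331.09efgh,39.15jk,3270.85ij
16812,,30.21bcde,2467.96rst,29.99stu,2514.4pqrs
16813,,22.46mn,1741.49defg,22.98xyz,1865.04abcdef
16814,,42.99kl,2600.77pqr,42.19hi,2983.3kl
16815,,36.1stuv,2825.58o,35.05no,3024.79kl
16816,,22.8lmn,1570.71hi,22.05yza,1863.46abcdef
16817,,35.68tuvw,2300.43uvw,34.07opq,2456.48rst
16818,,25.47ijk,1640.72ghi,25.13wx,1931zabcd
16819,**,63.57b,3893.9c,62.43b,4430.8b
16821,,24.41klm,1613.06ghi,23.56xy,1719.4efg
16822,,29.58bcdefg,1901.39bcd,29.1tuv,1907.54abcde
16834,,15.26q,1111.38m,14.43c,1177.9j
16835,,19.25p,1377.79kl,18.14b,1413.72i
16836,,21.56no,1525.72ij,20.33a,1778.28cdef
16837,,27.5ghi,1835.66cde,24.92x,1908.07abcde
16838,,19.35op,1372.03kl,19.98ab,1320.31ij
16839,**,48.09ij,3199.29hijk,46.91fg,3567.88fgh
16840,,30.84zabcd,2036.14yzab,28.66tuv,2081.19vwxyza
16902,,23.33klmn,1578.78hi,21.98yza,1739.71defg
18438,*,42.39klmn,2958.7no,40.76ij,3718.42ef
18448,*,40.05nop,2966.61no,38.12kl,3115.94jk
18662,,2.65t,151.77p,2.47f,139.56m
15743,,39.93nop,2530.31pqrs,37.49klmn,2501.03qrs
BAGCE 100,**,54.21ef,3101.07jklmn,55.11d,3684.03ef
BAGCE 17,*,37.38qrst,3016.64lmn,37.57klm,3215.17ijk
BAGCE 30,**,59.94c,4130.07b,58.37c,4466.59b
BAGCE 34,**,52.51fg,3145.92ijklm,51.03e,3750.61def
BAGCE 53,*,42.74klm,2976.08no,41.28hij,3348.2hij
BAGCE 81,*,39.02opqr,2943.12no,37.75kl,3163.11jk
BAGCE 86,,36.58rstu,2600.97pqr,35.22mno,2518.56pqrs
BAGCE 93,**,52.27fg,3818.98cd,50.94e,4469.65b
BAGCE 97,*,43.35k,3256.66ghij,42.43hi,3631.1efg
CNPGL 00-1-1,**,48.86ij,3697.89d,45.97g,3520.77fgh
CNPGL 92-133-3,,30.88zabcd,2165.94wxy,30.88rst,2711.36mnopq
CNPGL 92-198-7,**,51.64gh,3381.83efg,49.35ef,4169.44c
CNPGL 92-56-2,**,47.63j,3156.48ijkl,46.1g,3541.91fgh
CNPGL 92-66-3,**,48.33ij,3053.45klmn,47.38fg,3422.05ghi
CNPGL 9279-2,,34.22vwx,2208.15vwx,31.57rs,2260.57tuv
CNPGL 93-37-5,**,56.71d,3479.82e,55.75d,3967.35cd
CNPGL 93-01-1,,27.66fghi,2138.5xyz,24.67x,2030.17wxyzab
CNPGL 93-04-2,*,39.51opq,2952.96no,39.58jk,3160.9jk
CNPGL 93-18-2,,26.6hij,2022.46yzab,24.62x,1831.22bcdef
CNPGL 94-13-1,,38.99opqr,2993.54mn,38.05kl,2735.53mnop
CNPGL 96-21-1,,28.93defgh,2094.59xyza,28.57tuv,2251.7tuvw
CNPGL 96-23-1,,23.5klmn,1698.31efgh,23.03xyz,1780.96cdef
CNPGL 96-27-3,,34.53uvwx,2374.71stu,33.08opqr,2345.12stu
Pioneiro,,35.18tuvw,2558.97pqr,34.15op,2797.11lmno
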